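---
title: "The SMD format: data model, content identifiers, and synthetic smFRET data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SMD format: data model, content identifiers, and synthetic smFRET data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdformat)
```

## The problem this package addresses

Single-molecule experiments — smFRET above all — produce one time series
per molecule, typically several channels recorded simultaneously (donor
and acceptor fluorescence, a derived FRET ratio) plus post-processing
products such as an idealized state trajectory from HMM fitting. Labs
store these traces in ad hoc Matlab structs, CSV dumps or binary vendor
formats, which makes it hard to move data between analysis tools or to
re-analyze published datasets. The single-molecule dataset (SMD) layout
addresses this with a small, language-neutral JSON structure:

* a **dataset** is one experiment: a description string `desc`,
  free-form annotations `attr`, a **type map** `types` declaring the
  scalar type of every channel, a list of traces in `data`, and a
  content identifier `id`;
* a **trace** is one molecule: exactly four fields — `index` (row
  labels, typically acquisition times in seconds), `values` (one array
  per channel), `attr` (per-trace annotations such as fitted
  parameters), and `id`.

Two structural rules carry most of the weight. First, *all traces in a
dataset share one fixed set of channels*, declared once in `types`;
this is what lets a viewer or fitting tool consume a dataset without
prior knowledge of the experiment. Second, *identifiers are content
hashes*: each `id` is the 32-digit lowercase hexadecimal MD5 digest of
the data it names, so a trace's identity follows its measurements, not
its filename.

```{r}
tr <- SMDTrace(index = c(0, 0.1, 0.2),
               values = list(donor = c(100, 90, 95),
                             acceptor = c(20, 25, 22)))
d <- SMDDataset(list(tr), desc = "one molecule, two channels")
d
```

## Canonical serialization: what exactly gets hashed

"MD5 of the data" is only well-defined given a byte-level convention.
The package fixes one canonical byte form and documents it here so that
other implementations can reproduce every identifier:

* UTF-8 JSON, no insignificant whitespace, object keys in ascending
  code-point order;
* whole numbers render bare (`2`, not `2.0`), provided they are
  exactly representable (|x| < 2^53; larger magnitudes fall back to the
  float form below);
* non-integer numbers render with the fewest significant digits in
  {15, 16, 17} whose C `%g` form re-parses to the identical double —
  checked against both `strtod` and the JSON parser used by the reader,
  whose decimal conversion can differ from `strtod` by one unit in the
  last place on short forms. Negative zero renders as `0`;
* strings escape `\`, `"`, and C0 controls (`\b \t \n \f \r`, other
  controls as `\u00XX`); non-ASCII text is raw UTF-8;
* `NA` renders as `null`. `NaN` and ±`Inf` have no JSON spelling and
  are rejected at serialization time with the offending JSON path —
  missing measurements must be encoded as `null` (channel `NA`), never
  as non-finite floats.

The two hash domains are deliberately different:

* **trace id** = MD5 over `{"index": ..., "values": ...}` only. The
  trace `attr` is excluded, so annotating a trace (fitted rates, QC
  flags) never changes its identity — annotations are products of
  analysis, while identity should track the raw measurements. The id
  never hashes itself.
* **dataset id** = MD5 over `{"attr": ..., "data": [...], "desc": ...,
  "types": ...}` with each trace embedded as
  `{"attr", "id", "index", "values"}` — trace ids included, the
  top-level id excluded. Editing dataset metadata therefore changes
  the dataset id but no trace id; editing any channel value changes
  both; reordering traces changes the dataset id because `data` is an
  ordered array.

Compact output of `writeSMD()` is exactly the canonical text plus a
trailing newline, so writing the same dataset twice is byte-identical;
`pretty = TRUE` re-indents for humans without affecting any id, since
ids hash canonical bytes, not file bytes. MD5 is used as a content
fingerprint, not a security primitive; it is retained because it is the
format's established convention.

```{r}
rawToChar(canonicalBytes(tr))
smdId(tr) == traceId(tr)
```

## Scalar types and promotion

Channels carry one of four scalar type tags: `bool`, `int`, `float`,
`string`. When a type map is not supplied, `inferTypes()` assigns each
channel the narrowest tag covering every observed value across traces,
with promotion order `bool < int < float`; any text value forces
`string`, and a channel mixing text with numbers has no common type and
is an error. `null` is legal in any channel regardless of tag (dropped
frames are routine in single-molecule acquisition) and carries no type
information. On dataset construction, channel storage is coerced to the
declared tag, and trace ids are recomputed if that changed any stored
value (for example a logical channel promoted to `int` is thereafter
stored, serialized and hashed as `0`/`1`).

An explicit `types` map is required for a zero-trace dataset — types
cannot be inferred from nothing. The `index` is restricted to finite
numbers: the format calls it "row labels", but times are the universal
case, and a numeric index is what keeps the table converters and the
simulator well-defined. Order violations are a warning, not an error,
since labels are not formally required to be sorted.

## Validation

`validateSMD()` checks a parsed document and returns a report of coded
issues in document order rather than stopping at the first defect; the
codes are the closed enumeration `SMD_ISSUE_CODES`, each with a
severity and a JSON path (1-based indices). `strict` mode is the
contract for data this package writes: all five top-level and four
trace fields present, no unknown keys, stored ids equal to recomputed
ids. `lenient` mode exists for files from tools that predate these
conventions: recoverable omissions (missing `desc`, `attr`, `types`,
ids) and unknown keys downgrade to warnings, `readSMD()` repairs them
(empty description, inferred types, recomputed ids, unknown keys moved
to an `x-`-prefixed attr entry), and an id mismatch downgrades from
`E_ID_MISMATCH` to `W_ID_MISMATCH`. Id verification is skipped
entirely when structural errors make the canonical hash ill-defined —
reporting a cascade of mismatches would only obscure the primary
defect.

Two validator choices are worth stating. Duplicate trace ids are a
warning, not an error: under content hashing, two genuinely identical
measurement series legitimately collide. And scientific plausibility
(FRET inside [0, 1], positive intensities) is deliberately out of
scope — that is analysis, not format.

The shipped conformance corpus
(`runConformance()`, files under `inst/extdata/conformance/`) pairs a
minimally corrupted fixture with the exact codes it must trigger, one
case per issue code plus valid, reformatted and lenient-mode cases, so
an independent implementation can test itself against the same files.

## Long-table conversion

`importLongTable()` / `exportLongTable()` translate between SMD and the
one-row-per-time-point tables that acquisition scripts produce. A
`longTableSpec()` names the trace-key, index, channel and optional
per-trace attribute columns; attribute columns must be constant within
a trace, the original key is kept as the `source_key` attr, and empty
cells map to `null`. Export writes numeric cells through the canonical
renderer so the table is lossless; per-trace attrs flatten one level
into dotted column names, and deeper nesting is refused rather than
silently mangled. Delimiters are auto-detected between comma and tab
with an override, and the decimal separator is fixed to `.` so parsing
does not depend on locale.

## Dataset algebra

`mergeDatasets()`, `filterTraces()`, `splitByAttr()`,
`attachChannel()` and `summarizeDataset()` all copy — content ids make
in-place mutation hazardous, so inputs are never modified — and every
output revalidates strictly with consistent ids. Merging requires
identical type maps and preserves trace ids (trace data is untouched).
Filtering accepts an R function or a small predicate language
(`"length >= 3"`, `"attr.snr > 2"`, `"attr.condition == 'A'"`,
`"id in [...]"`); a predicate naming an attr a trace lacks simply
excludes that trace. `attachChannel()` adds a derived channel — the
idealized trajectory use case — which necessarily changes every trace
id; each trace's previous id is kept in its attr under `prior_id`, so
provenance survives the identity change.

## The simulator: what it emulates and what it does not

`simulateTrace()` / `simulateDataset()` generate the data the format is
designed to hold: a discrete-time K-state Markov chain observed through
noisy donor/acceptor intensities, with the FRET ratio computed from the
*noisy* intensities (so its fluctuations are realistic and
anti-correlated between channels) and the true state path stored as an
integer channel — raw channels plus an idealized trajectory in one
trace. Frames with non-positive total intensity get a `null` FRET value
and are counted in the trace attr.

Defaults, chosen once as a typical two-state folding system at camera
frame rates and kept fixed:

| parameter | default | meaning |
|---|---|---|
| `A` | `[[0.98, 0.02], [0.05, 0.95]]` | per-frame transition matrix; mean dwells 50 and 20 frames |
| `pi0` | stationary distribution of `A` (5/7, 2/7) | molecules at equilibrium when recording starts |
| `dt` | 0.1 s | 10 Hz acquisition |
| `donorMean`, `acceptorMean` | (2000, 8000), (8000, 2000) | FRET ≈ 0.8 in state 0, ≈ 0.2 in state 1 |
| `noiseSd` | 300 | per-channel Gaussian noise, SNR ≈ 10 on total intensity |

Reproducibility is part of the contract: the master seed seeds the RNG
once, child seeds are drawn with `sample.int(2147483646, nTraces)`, and
trace *i* is simulated under child seed *i* — equal seeds give
byte-identical files and equal content ids.

The simulator is a per-frame chain, not continuous-time kinetics with
exponential dwells; frames are the format's native sampling, and
geometric dwells are the discrete counterpart of the exponential ones.
It has no photobleaching, blinking, camera (EMCCD gain) noise model, or
intensity drift, and HMM inference from the noisy channels is
explicitly out of scope. Consequently, passing tests demonstrate that
the *format machinery* (hashing, IO, validation, algebra) behaves
correctly on realistic trace shapes — they say nothing about any
inference method's behavior on real experimental noise.

`recoverKinetics()` closes the simulate-and-verify loop from the *true*
state channel: pooled transition counts, row-normalized without
pseudocounts (zero-count rows are reported undefined rather than
smoothed), plus pooled occupancy. The verification thresholds use the
estimators' actual sampling distributions: transition probabilities are
conditionally binomial given the row counts, so each entry gets a
binomial standard error; pooled occupancy samples are autocorrelated,
so its standard error carries the chain's asymptotic variance inflation
(1 + λ₂)/(1 − λ₂), with λ₂ the second eigenvalue of `A` (0.93 at the
defaults — ignoring it would understate the standard error roughly
five-fold). Mean dwell times are compared against 1/(1 − A[i,i]) with a
small allowance for the bias introduced by dwells censored at trace
boundaries.

Test problem sizes were chosen to make these sampling-error bounds
tight while keeping the whole suite quick: the id-format check pools
1,000 short traces; the round-trip property runs 200 generated
datasets; kinetic recovery uses 50 traces × 2,000 frames (10⁵ pooled
frames, giving standard errors of ~5 × 10⁻⁴ on transition entries and
~7.5 × 10⁻³ on occupancy).

## Numerical and degenerate-input choices

* Empty traces (zero rows) and zero-trace datasets are valid; an empty
  channel infers the bottom of the numeric lattice.
* R has no scalar/array distinction, so attrs follow a fixed mapping:
  length-1 unnamed vectors are JSON scalars, longer vectors are
  arrays, named lists are objects, and empty containers inside `attr`
  are `{}` (attrs are maps). A length-1 unnamed *list* stays an array,
  which is how single-element JSON arrays in foreign files survive a
  round trip.
* Uppercase hex ids in input are accepted, normalized to lowercase and
  warned about; the package always emits lowercase.
* A file is one experiment: a bare JSON array of traces (no outer
  structure) is rejected, because the outer object is what carries
  `types`, `desc` and the dataset id.

## Known limitations

* Reading is whole-file; multi-gigabyte streaming and HDF5/.MAT/XML
  containers are out of scope.
* Empty atomic vectors inside `attr` serialize as `[]` but read back
  as empty maps; avoid zero-length attr arrays.
* Channel deletion/renaming and trace resampling onto a common index
  are intentionally not provided.
* Extraction of traces from raw movies is upstream of this format:
  SMD begins at the trace level.
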