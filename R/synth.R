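## Synthetic smFRET trace generator: a discrete-time K-state Markov
## chain observed through noisy donor/acceptor intensities, a derived
## FRET ratio channel, and the true state path stored as the idealized
## trajectory channel. The simulator exists so that every component of
## the package can be exercised on fully synthetic, reproducible data.

#' Construct a kinetic model for the trace simulator
#'
#' Defaults describe a two-state folder observed at 10 Hz: per-frame
#' transition probabilities `A = [[0.98, 0.02], [0.05, 0.95]]` (mean
#' dwells of 50 and 20 frames), initial distribution equal to the
#' stationary distribution of `A` (molecules are at equilibrium when
#' recording starts), frame interval `dt = 0.1` s, and emission means
#' giving FRET values of 0.8 (state 0, donor 2000 / acceptor 8000) and
#' 0.2 (state 1, donor 8000 / acceptor 2000) with Gaussian channel
#' noise of sd 300 (signal-to-noise of roughly 10 on total intensity).
#'
#' @param A K x K row-stochastic per-frame transition matrix.
#' @param pi0 initial state distribution; defaults to the stationary
#'   distribution of `A`.
#' @param dt frame interval, seconds.
#' @param donorMean,acceptorMean per-state emission means (arbitrary
#'   intensity units), length K.
#' @param noiseSd Gaussian emission noise sd, both channels.
#' @return A [KineticModel-class].
#' @examples
#' kineticModel()
#' @export
kineticModel <- function(A = matrix(c(0.98, 0.02, 0.05, 0.95), 2L, 2L,
                                    byrow = TRUE),
                         pi0 = NULL, dt = 0.1,
                         donorMean = c(2000, 8000),
                         acceptorMean = c(8000, 2000),
                         noiseSd = 300) {
  A <- as.matrix(A)
  if (is.null(pi0)) pi0 <- stationaryDistribution(A)
  new("KineticModel", A = A, pi0 = as.numeric(pi0), dt = as.numeric(dt),
      donorMean = as.numeric(donorMean),
      acceptorMean = as.numeric(acceptorMean),
      noiseSd = as.numeric(noiseSd))
}

#' Stationary distribution of a transition matrix
#'
#' Solves `pi A = pi`, `sum(pi) = 1` for a row-stochastic matrix.
#'
#' @param A K x K row-stochastic matrix.
#' @return Numeric vector of length K.
#' @examples
#' stationaryDistribution(matrix(c(0.98, 0.02, 0.05, 0.95), 2, byrow = TRUE))
#' @export
stationaryDistribution <- function(A) {
  A <- as.matrix(A)
  K <- nrow(A)
  M <- t(diag(K) - A)
  M[K, ] <- 1
  pi <- solve(M, c(rep(0, K - 1L), 1))
  pi / sum(pi)
}

.modelAttr <- function(model) {
  list(
    sim_K = nrow(model@A),
    sim_dt = model@dt,
    sim_A = as.vector(t(model@A)),  # row-major
    sim_pi0 = model@pi0,
    sim_donor_mean = model@donorMean,
    sim_acceptor_mean = model@acceptorMean,
    sim_noise_sd = model@noiseSd)
}

#' Simulate one smFRET trace
#'
#' Samples a state path from the model's Markov chain (initial state
#' from `pi0`, then per-frame transitions from `A`) and emits four
#' channels: `donor` and `acceptor` raw intensities (state mean plus
#' Gaussian noise), `fret` computed as acceptor / (donor + acceptor)
#' from the *noisy* intensities — so its noise is realistic and
#' correlated with the raw channels — and `state`, the true 0-based
#' state path (the idealized trajectory). Frames where the total
#' intensity is not positive get a null `fret` value; their count is
#' recorded in the trace attr as `n_fret_null`. The index is
#' `0, dt, 2 dt, ...` seconds. The seed and the flattened model
#' parameters are recorded in the trace attr.
#'
#' @param model a [KineticModel-class].
#' @param nPoints number of frames (>= 1).
#' @param seed optional integer seed; with equal seed and model the
#'   trace (and hence its content id) is bit-identical across runs.
#' @return An [SMDTrace-class] with channels donor, acceptor, fret,
#'   state.
#' @examples
#' tr <- simulateTrace(kineticModel(), nPoints = 100, seed = 7)
#' channelNames(tr)
#' @export
simulateTrace <- function(model = kineticModel(), nPoints, seed = NULL) {
  validObject(model)
  nPoints <- as.integer(nPoints)
  if (is.na(nPoints) || nPoints < 1L)
    stop("'nPoints' must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  K <- nrow(model@A)
  s <- integer(nPoints)
  s[1L] <- sample.int(K, 1L, prob = model@pi0)
  if (nPoints > 1L) {
    u <- stats::runif(nPoints - 1L)
    cumA <- t(apply(model@A, 1L, cumsum))
    for (t in 2:nPoints) {
      s[t] <- 1L + sum(u[t - 1L] > cumA[s[t - 1L], ])
    }
  }
  donor <- model@donorMean[s] + stats::rnorm(nPoints, 0, model@noiseSd)
  acceptor <- model@acceptorMean[s] + stats::rnorm(nPoints, 0, model@noiseSd)
  tot <- donor + acceptor
  fret <- ifelse(tot > 0, acceptor / tot, NA_real_)
  nFretNull <- sum(tot <= 0)
  at <- c(if (!is.null(seed)) list(seed = as.integer(seed)),
          .modelAttr(model),
          list(n_fret_null = as.integer(nFretNull)))
  SMDTrace(
    index = model@dt * (seq_len(nPoints) - 1L),
    values = list(donor = donor, acceptor = acceptor, fret = fret,
                  state = as.numeric(s - 1L)),
    attr = at)
}

#' Simulate an smFRET dataset
#'
#' Simulates `nTraces` traces from one kinetic model. Reproducibility
#' scheme (part of the public contract): the master seed seeds R's RNG
#' once, one child seed per trace is drawn with
#' `sample.int(2147483646, nTraces)`, and trace `i` is generated by
#' [simulateTrace()] under child seed `i`. Equal master seeds therefore
#' give bit-identical datasets (equal content ids); the model
#' parameters, master seed and dimensions are recorded in the
#' top-level attr.
#'
#' @param model a [KineticModel-class].
#' @param nTraces number of traces (>= 1).
#' @param nPoints frames per trace.
#' @param seed integer master seed.
#' @param desc dataset description.
#' @return A strictly valid [SMDDataset-class].
#' @examples
#' d <- simulateDataset(nTraces = 3, nPoints = 50, seed = 42)
#' summarizeDataset(d)$nPointsTotal
#' @export
simulateDataset <- function(model = kineticModel(), nTraces, nPoints,
                            seed = 1L, desc = "simulated smFRET dataset") {
  validObject(model)
  nTraces <- as.integer(nTraces)
  if (is.na(nTraces) || nTraces < 1L)
    stop("'nTraces' must be a positive integer", call. = FALSE)
  set.seed(as.integer(seed))
  childSeeds <- sample.int(2147483646L, nTraces)
  tracesList <- lapply(seq_len(nTraces), function(i) {
    simulateTrace(model, nPoints, seed = childSeeds[i])
  })
  at <- c(list(seed = as.integer(seed), n_traces = nTraces,
               n_points = as.integer(nPoints)),
          .modelAttr(model))
  SMDDataset(tracesList, desc = desc, attr = at,
             types = c(donor = "float", acceptor = "float",
                       fret = "float", state = "int"))
}

#' Recover transition statistics from an idealized state channel
#'
#' Closes the simulate-and-verify loop: reads the *true* state channel
#' (no HMM inference is performed) and estimates the per-frame
#' transition matrix by maximum likelihood — pooled transition counts,
#' row-normalized with no pseudocount — together with pooled state
#' occupancy fractions. Rows with zero outgoing transitions are
#' reported as undefined (`NaN`).
#'
#' @param dataset an [SMDDataset-class].
#' @param stateChannel name of the integer state channel (values
#'   0..K-1).
#' @param K number of states; defaults to `max(state) + 1`.
#' @return A list: `A` (estimated K x K matrix), `occupancy` (length
#'   K), `counts` (transition count matrix), `nFrames` (total frames
#'   pooled), `undefinedRows` (indices of zero-count rows).
#' @examples
#' d <- simulateDataset(nTraces = 5, nPoints = 200, seed = 1)
#' recoverKinetics(d)$A
#' @export
recoverKinetics <- function(dataset, stateChannel = "state", K = NULL) {
  stopifnot(is(dataset, "SMDDataset"))
  if (!stateChannel %in% names(dataset@types))
    stop(sprintf("no channel named '%s'", stateChannel), call. = FALSE)
  paths <- lapply(dataset@data, function(tr) {
    v <- tr@values[[stateChannel]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != trunc(v)))
      stop(sprintf(
        "state channel '%s' must hold integer states (trace %s)",
        stateChannel, tr@id), call. = FALSE)
    as.integer(v)
  })
  allStates <- unlist(paths, use.names = FALSE)
  if (any(allStates < 0L))
    stop("state labels must be non-negative integers (0-based)",
         call. = FALSE)
  if (is.null(K)) K <- max(allStates) + 1L
  counts <- matrix(0, K, K)
  for (s in paths) {
    n <- length(s)
    if (n < 2L) next
    from <- s[-n] + 1L; to <- s[-1L] + 1L
    counts <- counts + table(factor(from, levels = seq_len(K)),
                             factor(to, levels = seq_len(K)))
  }
  counts <- unclass(as.matrix(counts))
  dimnames(counts) <- NULL
  rows <- rowSums(counts)
  A <- counts / rows  # rows with zero counts become NaN
  occupancy <- tabulate(allStates + 1L, nbins = K) / length(allStates)
  list(A = A, occupancy = occupancy, counts = counts,
       nFrames = length(allStates),
       undefinedRows = which(rows == 0))
}

#' Dwell times of an idealized state channel
#'
#' Run lengths (in frames) of consecutive identical states, pooled over
#' traces; censored first/last dwells are included. For an ergodic
#' chain the mean dwell in state i approaches `1 / (1 - A[i, i])`
#' frames.
#'
#' @inheritParams recoverKinetics
#' @return A list with one numeric vector of run lengths per state,
#'   named by 0-based state label.
#' @export
dwellTimes <- function(dataset, stateChannel = "state", K = NULL) {
  stopifnot(is(dataset, "SMDDataset"))
  runsByState <- list()
  for (tr in dataset@data) {
    v <- as.integer(tr@values[[stateChannel]])
    if (!length(v)) next
    r <- rle(v)
    for (j in seq_along(r$values)) {
      key <- as.character(r$values[j])
      runsByState[[key]] <- c(runsByState[[key]], r$lengths[j])
    }
  }
  if (is.null(K)) return(runsByState[order(as.integer(names(runsByState)))])
  out <- stats::setNames(vector("list", K), as.character(0:(K - 1L)))
  for (k in names(out))
    out[[k]] <- if (is.null(runsByState[[k]])) numeric() else runsByState[[k]]
  out
}
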