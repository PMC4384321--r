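{"attr":{},"data":[{"attr":{},"id":"be4a8a6b05a62f65ca33edec6438cd0c","index":[0,0.1],"values":{"fret":[0.4,0.6]}},{"attr":{},"id":"be4a8a6b05a62f65ca33edec6438cd0c","index":[0,0.1],"values":{"fret":[0.4,0.6]}}],"desc":"identical molecules","id":"078b5d34909d7e13c30f3debcd11468a","types":{"fret":"float"}}
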