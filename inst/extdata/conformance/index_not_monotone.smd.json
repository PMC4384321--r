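{"attr":{},"data":[{"attr":{},"id":"22fbe5c7199a3c7983435ffb0cf40852","index":[0.2,0.1,0],"values":{"fret":[0.1,0.5,0.9]}}],"desc":"non-monotone index","id":"2bdde02f6a30cd482b1c4ef3f98b8949","types":{"fret":"float"}}
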