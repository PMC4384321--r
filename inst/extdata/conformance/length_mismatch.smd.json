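{"attr":{"instrument":"synthetic","temperature_C":22},"data":[{"attr":{"condition":"10mM","snr":4.2},"id":"6ae5dc3eaca8c5c309d412728b711356","index":[0,0.1,0.2],"values":{"acceptor":[20,25.75,22],"donor":[100.5,90.25],"state":[0,1,1]}},{"attr":{"condition":"20mM","snr":2.1},"id":"34a51006ae0d1733264db5fa5340cbd6","index":[0,0.1],"values":{"acceptor":[30.25,28],"donor":[80,85.5],"state":[1,0]}}],"desc":"conformance base dataset","id":"0be58c237d838861156b47351f0dc436","types":{"acceptor":"float","donor":"float","state":"int"}}
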