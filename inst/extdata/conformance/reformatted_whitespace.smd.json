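{
  "types": {
    "acceptor": "float",
    "donor": "float",
    "state": "int"
  },
  "id": "0be58c237d838861156b47351f0dc436",
  "desc": "conformance base dataset",
  "data": [
    {
      "values": {
        "acceptor": [
          20,
          25.75,
          22
        ],
        "donor": [
          100.5,
          90.25,
          95
        ],
        "state": [
          0,
          1,
          1
        ]
      },
      "index": [
        0,
        0.10000000000000001,
        0.20000000000000001
      ],
      "id": "6ae5dc3eaca8c5c309d412728b711356",
      "attr": {
        "condition": "10mM",
        "snr": 4.2000000000000002
      }
    },
    {
      "values": {
        "acceptor": [
          30.25,
          28
        ],
        "donor": [
          80,
          85.5
        ],
        "state": [
          1,
          0
        ]
      },
      "index": [
        0,
        0.10000000000000001
      ],
      "id": "34a51006ae0d1733264db5fa5340cbd6",
      "attr": {
        "condition": "20mM",
        "snr": 2.1000000000000001
      }
    }
  ],
  "attr": {
    "instrument": "synthetic",
    "temperature_C": 22
  }
}
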