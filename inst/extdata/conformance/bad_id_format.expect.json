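{"mode":"strict","expected_codes":"E_BAD_ID_FORMAT","expected_valid":false}
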