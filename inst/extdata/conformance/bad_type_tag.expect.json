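{"mode":"strict","expected_codes":"E_BAD_TYPE_TAG","expected_valid":false}
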