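{"mode":"strict","expected_codes":"I_NULL_VALUE","expected_valid":true}
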