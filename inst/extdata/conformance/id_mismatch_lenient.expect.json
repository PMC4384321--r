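{"mode":"lenient","expected_codes":"W_ID_MISMATCH","expected_valid":true}
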