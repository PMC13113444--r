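bef5ea0433988b2ed518d65edad706aa generic_body_model.json
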