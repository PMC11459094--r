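CNCC(O)c1ccc(O)c(O)c1
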