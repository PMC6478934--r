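mz,intensity
1680.59,1
1283.56,1
1070.46,1
843.37,1
632.23,1
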