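C00025 C00217
C00064 C00819
C00217 C00819
C00025 C00064
C00026 C00217
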