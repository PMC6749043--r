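C00041 C00025
C00049 C00025
C00152 C00049
C00064 C00025
C00025 C00026
C00049 C00122
C00049 C00036
C00026 C00036
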