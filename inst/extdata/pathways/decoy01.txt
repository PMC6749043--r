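C00158 C00311
C00311 C00026
C00026 C00042
C00042 C00122
C00122 C00149
C00149 C00036
C00036 C00158
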