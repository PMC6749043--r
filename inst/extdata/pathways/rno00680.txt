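C00132 C00067
C00067 C00058
C00058 C00011
C00065 C00037
C00037 C00067
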