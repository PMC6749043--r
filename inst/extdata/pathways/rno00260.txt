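C00188 C00037
C00037 C00065
C00065 C00197
C00114 C00719
C00719 C01026
C01026 C00213
C00213 C00037
C00065 C00022
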