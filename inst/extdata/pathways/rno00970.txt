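C00886 C00041
C00886 C00025
C00886 C00064
C00886 C00073
C00886 C00065
C00886 C00188
C00886 C00082
C00886 C00183
C00886 C00152
C00886 C00037
C00886 C00049
C00886 C00135
C00886 C00407
C00886 C00123
C00886 C00047
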