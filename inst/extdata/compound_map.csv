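metabolite,kegg_id
Isoleucine,C00407
3-aminoisobutyrate,C01205
3-Hydroxybutyrate,C01089
Alanine,C00041
Asparagine,C00152
Aspartate,C00049
Betaine,C00719
choline,C00114
cytidine,C00475
formate,C00058
Fumarate,C00122
glucose,C00031
glutamate,C00025
glutamine,C00064
glycerol,C00116
glycine,C00037
lactate,C00186
LDL/VLDL,NA
Lipids,NA
Lysine,C00047
methionine,C00073
myo-Inositol,C00137
pyruvate,C00022
serine,C00065
threonine,C00188
"N,N-dimethylglycine",C01026
tyrosine,C00082
valine,C00183
citrate,C00158
creatine,C00300
histidine,C00135
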