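metabolite,shift,multiplicity,relative_area,base_level,integrate
Isoleucine,0.94,t,0.5,1.0,1
Isoleucine,1.01,d,0.5,1.0,0
3-aminoisobutyrate,1.23,d,1.0,1.0,1
3-Hydroxybutyrate,2.31,m,0.333333,1.0,1
3-Hydroxybutyrate,2.41,m,0.333333,1.0,0
3-Hydroxybutyrate,4.16,m,0.333334,1.0,0
Alanine,1.48,d,1.0,1.0,1
Asparagine,2.87,m,0.5,1.0,1
Asparagine,2.96,m,0.5,1.0,0
Aspartate,2.69,s,1.0,1.0,1
Betaine,3.27,s,0.5,1.0,0
Betaine,3.91,s,0.5,1.0,1
choline,3.20,s,1.0,1.0,1
cytidine,6.07,d,1.0,0.3,1
formate,8.46,s,1.0,0.3,1
Fumarate,6.53,s,1.0,0.3,1
glucose,3.42,t,0.166667,3.0,1
glucose,3.54,dd,0.166667,3.0,0
glucose,3.72,t,0.166667,3.0,0
glucose,3.74,m,0.166667,3.0,0
glucose,3.84,m,0.166667,3.0,0
glucose,5.24,d,0.166665,3.0,0
glutamate,2.08,m,0.333333,1.0,1
glutamate,2.15,m,0.333333,1.0,0
glutamate,2.35,m,0.333334,1.0,0
glutamine,2.14,m,0.333333,1.0,0
glutamine,2.45,m,0.333333,1.0,1
glutamine,3.80,m,0.333334,1.0,0
glycerol,3.58,m,0.333333,1.0,1
glycerol,3.66,m,0.333333,1.0,0
glycerol,3.80,m,0.333334,1.0,0
glycine,3.56,s,1.0,1.0,1
lactate,1.33,s,0.5,1.5,0
lactate,4.11,q,0.5,1.5,1
LDL/VLDL,0.89,br,0.333333,2.5,1
LDL/VLDL,1.31,br,0.333333,2.5,0
LDL/VLDL,1.57,br,0.333334,2.5,0
Lipids,2.10,br,0.333333,2.0,1
Lipids,2.24,br,0.333333,2.0,0
Lipids,5.31,br,0.333334,2.0,0
Lysine,1.86,m,0.25,1.0,1
Lysine,1.88,m,0.25,1.0,0
Lysine,3.03,t,0.25,1.0,0
Lysine,3.76,t,0.25,1.0,0
methionine,2.14,s,0.5,1.0,0
methionine,2.64,t,0.5,1.0,1
myo-Inositol,3.28,t,0.333333,1.0,0
myo-Inositol,3.63,t,0.333333,1.0,1
myo-Inositol,4.07,t,0.333334,1.0,0
pyruvate,2.37,s,1.0,1.0,1
serine,3.83,m,0.5,1.0,1
serine,3.98,m,0.5,1.0,0
threonine,4.28,m,1.0,1.0,1
"N,N-dimethylglycine",2.93,s,1.0,1.0,1
tyrosine,6.89,d,0.5,1.0,1
tyrosine,7.19,d,0.5,1.0,0
valine,0.99,d,0.333333,1.0,1
valine,1.04,d,0.333333,1.0,0
valine,2.27,m,0.333334,1.0,0
citrate,2.56,d,0.5,1.0,1
citrate,2.67,d,0.5,1.0,0
creatine,3.04,s,0.5,1.0,0
creatine,3.93,s,0.5,1.0,1
histidine,3.99,m,0.5,1.0,0
histidine,7.07,m,0.5,1.0,1
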