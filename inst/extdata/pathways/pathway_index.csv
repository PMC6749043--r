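id,name,file,decoy
rno00970,Aminoacyl-tRNA biosynthesis,rno00970.txt,0
rno00250,"Alanine, aspartate and glutamate metabolism",rno00250.txt,0
rno00471,D-Glutamine and D-glutamate metabolism,rno00471.txt,0
rno00270,Cysteine and methionine metabolism,rno00270.txt,0
rno00260,"Glycine, serine and threonine metabolism",rno00260.txt,0
rno00400,"Phenylalanine, tyrosine and tryptophan biosynthesis",rno00400.txt,0
rno00680,Methane metabolism,rno00680.txt,0
rno00290,"Valine, leucine and isoleucine biosynthesis",rno00290.txt,0
rno00562,Inositol phosphate metabolism,rno00562.txt,0
rno00350,Tyrosine metabolism,rno00350.txt,0
decoy01,Citrate cycle (decoy),decoy01.txt,1
decoy02,Purine metabolism (decoy),decoy02.txt,1
decoy03,Pentose phosphate pathway (decoy),decoy03.txt,1
decoy04,Butanoate metabolism (decoy),decoy04.txt,1
decoy05,Taurine and hypotaurine metabolism (decoy),decoy05.txt,1
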