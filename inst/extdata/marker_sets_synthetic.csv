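subtype,marker
epithelial,EPCAM
epithelial,KRT8
epithelial,KRT18
epithelial,KRT19
epithelial,CDH1
epithelial,CLDN4
muscle,DES
muscle,ACTN2
muscle,MYH1
muscle,TNNT2
muscle,MYOG
muscle,TTN
adipose,ADIPOQ
adipose,LEP
adipose,PLIN1
adipose,FABP4
adipose,CFD
neuronal,TUBB3
neuronal,MAP2
neuronal,SYP
neuronal,NEFL
neuronal,ENO2
neuronal,GFAP
connective,COL1A1
connective,COL1A2
connective,COL3A1
connective,FN1
connective,VIM
lymphoid,PTPRC
lymphoid,CD68
lymphoid,CD19
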