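effector,class_id,kd_um,domains
ARAF,1,0.07,
BRAF,1,,
RAF1,1,,
PIK3CA,2,,
PIK3CB,2,,
PIK3CD,2,7.5,
PIK3CG,2,,
PIK3C2B,2,,
PIK3C2G,2,,
PIK3C2A,2,,
RALGDS,3,,
RGL1,3,,
RGL2,3,,
RGL3,3,,
RGL4,3,,
MLLT4,4,3.03,PDZ
PLCE1,5,,C2
RIN1,6,,SH2
RIN2,6,,SH2
RIN3,6,,SH2
SNX27,6,10,PDZ
TIAM1,7,,PDZ;PH
TIAM2,7,,PDZ;PH
ARHGAP20,7,,PH
ARAP1,7,7.5,PH
ARAP2,7,,PH
ARAP3,7,,PH
DGKQ,7,,C1
RASSF1,8,,
RASSF10,8,,
RASSF2,8,,
RASSF3,8,,
RASSF4,8,,
RASSF5,8,,
RASSF6,8,,
RASSF7,8,,
RASSF8,8,,
RASSF9,8,,
RAPGEF2,9,,PDZ
RAPGEF3,9,,
RAPGEF4,9,,
RAPGEF5,9,,
RAPGEF6,9,,PDZ
KRIT1,9,,PH
RASIP1,9,,
RADIL,9,7.5,PDZ
APBB1IP,9,,
RAPH1,9,,PH
MYO9A,10,7.5,
MYO9B,10,,
MYO10,10,,PH
RGS12,11,,PDZ
RGS14,11,,
GRB7,12,,SH2;PH
GRB10,12,,SH2;PH
GRB14,12,,SH2;PH
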