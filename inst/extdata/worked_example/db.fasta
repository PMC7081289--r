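>IEDB_GA
GAAAAA
>IEDB_NEF
SIINFEKL
>IEDB_FLU
GILGFVFTL
>IEDB_CMV
NLVPMVATV
>IEDB_EBV
RAKFKQLL
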