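id	betahat	sebetahat
g01	2.2872	1
g02	-1.1968	1
g03	-0.6943	1
g04	-0.4123	1
g05	-0.9707	1
g06	-3.9473	1
g07	-1.2519	1
g08	1.3830	1
g09	2.6527	1
g10	6.1900	1
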