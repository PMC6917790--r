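# Duplex initiation and symmetry terms, unified set (SantaLucia 1998)
# term: init_AT = per terminal A.T pair; init_GC = per terminal G.C pair; sym = self-complementary correction
# table_version: wc-unified-1998.1
term	dH	dS
init_AT	2.3	4.1
init_GC	0.1	-2.8
sym	0	-1.4
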