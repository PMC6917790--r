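# Hairpin loop initiation penalties, dG37 kcal/mol by loop size (nt)
# Representative values after SantaLucia & Hicks Annu Rev Biophys 2004; treated as purely entropic (dH = 0)
# sizes between/beyond table rows: Jacobson-Stockmayer extrapolation dG(n) = dG(x) + 2.44*R*310.15*ln(n/x)
# table_version: hairpin-loop-2004.1
loop_size	dG37
3	3.5
4	3.5
5	3.3
6	4.0
7	4.2
8	4.3
9	4.5
10	4.4
12	4.7
14	4.9
16	5.0
18	5.2
20	5.3
25	5.6
30	5.9
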