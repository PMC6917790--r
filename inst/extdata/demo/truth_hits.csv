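"oligo_name","contig_id","strand","start","end","mismatches"
"amrA_F","c1","+",301,320,0
"amrA_P","c1","+",361,380,0
"amrA_R","c1","-",520,539,1
"blaT_F","c1","+",1200,1219,0
"blaT_F","c2","+",401,420,0
"blaT_F","c2","+",431,450,0
"blaT_P","c2","+",500,519,0
"amrA_P","c2","-",540,559,0
"blaT_R","c2","-",700,719,0
"vanX_F","c3","+",250,269,0
"vanX_R","c3","-",450,469,0
"amrA_R","c3","-",800,819,0
"blaT_P","c3","+",1100,1119,0
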