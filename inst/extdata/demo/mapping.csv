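"oligo_name","gene_name","expected_product_size","resistance"
"amrA_F","amrA",239,"aminoglycoside"
"amrA_R","amrA",239,"aminoglycoside"
"amrA_P","amrA",,"aminoglycoside"
"blaT_F","blaT",319,"beta-lactam"
"blaT_R","blaT",319,"beta-lactam"
"blaT_P","blaT",,"beta-lactam"
"vanX_F","vanX",,"glycopeptide"
"vanX_R","vanX",,"glycopeptide"
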