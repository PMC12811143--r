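genotype_label,tbx5_dose,gene_dose,affected,total
WT,0,0,0,14
Tbx5_del_het,1,0,5,8
Slit2_het,0,1,1,8
Slit2_hom,0,2,3,4
Tbx5_del_het_Slit2_het,1,1,5,8
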