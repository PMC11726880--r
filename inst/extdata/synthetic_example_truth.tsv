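gene	is_de	direction	effect_size	affected
gene_01	FALSE	none	      0	
gene_02	TRUE	down	      3	case_01,case_02,case_03,case_04,case_05
gene_03	FALSE	none	      0	
gene_04	FALSE	none	      0	
gene_05	FALSE	none	      0	
gene_06	TRUE	down	      3	case_01,case_02,case_03,case_04,case_05
gene_07	TRUE	up	      3	case_01,case_02,case_03,case_04,case_05
gene_08	FALSE	none	      0	
gene_09	TRUE	up	      3	case_01,case_02,case_03,case_04,case_05
gene_10	FALSE	none	      0	
gene_11	FALSE	none	      0	
gene_12	FALSE	none	      0	
gene_13	FALSE	none	      0	
gene_14	FALSE	none	      0	
gene_15	FALSE	none	      0	
gene_16	FALSE	none	      0	
gene_17	FALSE	none	      0	
gene_18	FALSE	none	      0	
gene_19	FALSE	none	      0	
gene_20	FALSE	none	      0	
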