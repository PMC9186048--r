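compound_id	name	kegg_id	formula	monoisotopic_mass
CPD0001	Glutamine	C00064	C5H10N2O3	NA
CPD0002	Piperettine	NA	C19H21NO3	NA
CPD0003	Piperine	C03882	C17H19NO3	NA
CPD0004	Dihydroxylated DDE derivative (formula inferred from name)	NA	C14H8Cl4O2	NA
CPD0005	p,p'-DDE	C14097	C14H8Cl4	NA
CPD0006	p,p'-DDT	C04623	C14H9Cl5	NA
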