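accession	entry_name	gene	peptide_id	sequence	start	end	regulation	preceding_residue	following_residue
P07196	NFL	NEFL	NFL	SFPSYYTSHVQEEQIEVEETIEAAKAEEA	438	466	Up	D	R
P46821	MAP1B	MAP1B	MAP1B_KE	KEPKKEIKKLPKDAKKSSTPLS	726	747	Up	F	E
P46821	MAP1B	MAP1B	MAP1B_EA	EAKKPAALKPKVPKKEESVKKDSVA	748	772	Up	S	L
P05976	MYL1	MYL1	MYL1	APKKDVKK(trimethylation)PVAAAAAAPAPAPAPAPAPAPAKPKEE	2	36	Up	M	Q
P02654	APOC1	APOC1	APOC1_SE	SETFQKVKEKLKIDS	69	83	Up	A	P
Q8N126	CADM3	CADM3	CADM3	TLNVNDPSPVPSSSSTY	313	329	Down	S	G
P05060	SCG1	CHGB	SCG1	EPRAYFMSDTREE	425	437	Down	R	D
P01210	PENK	PENK	PENK	ADGTSTLRENSKPEESHLL	79	96	Down	H	L
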