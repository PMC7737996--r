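# category table: printed per-category antibody counts (overlaps in parentheses in the source)
category	declared_count	declared_overlap	pathway_group
Proliferation-related proteins	11	0	1
cMyc/MAX/MAD network	4	1	1
p53/Rb/E2F signaling	4	1	1
Wnt/beta-catenin signaling	7	0	1
Epigenetic modification	7	0	1
Protein translation	7	0	1
Growth factor	20	0	1
RAS signaling proteins	21	0	1
NFkB signaling proteins	19	11	1
Upregulated inflammatory proteins	20	0	1
Downregulated inflammatory proteins	25	0	1
p53-mediated apoptosis	15	1	1
FAS-mediated apoptosis	9	1	1
Protection- and survival-related proteins	20	4	1
Differentiation-related proteins	18	1	1
Endoplasmic reticulum stress-related proteins	11	10	1
Oncogenesis-related proteins	17	2	1
Angiogenesis-related proteins	23	9	1
Osteogenesis-related proteins	17	5	1
Control housekeeping proteins	3	0	0
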