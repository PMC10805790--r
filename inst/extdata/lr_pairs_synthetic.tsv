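pair_id	ligand_gene	receptor_gene
P01	Pdgfa	Pdgfra
P02	Pdgfb	Pdgfrb
P03	Dll4	Notch3
P04	Jag1	Notch3
P05	Vegfa	Kdr
P06	Angpt1	Tek
P07	Wnt5a	Fzd1
P08	Tgfb1	Tgfbr2
P09	Fgf10	Fgfr2
P10	Cxcl12	Cxcr4
P11	Wnt2	Fzd1
P12	Tgfb1	Tgfbr3
P13	Pdgfb	Pdgfra
P14	Pdgfa	Pdgfrb
P15	Jag1	Notch2
P16	Vegfa	Flt1
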