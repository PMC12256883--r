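Synthetic example of the FoldX BuildModel "Dif_" energy-difference dialect.
Values are invented for format illustration; they are not FoldX output.
Pdb	total energy	Backbone Hbond	Sidechain Hbond	Van der Waals
VA310M.pdb	1.234	0.10	-0.05	0.42
GA317R.pdb	2.501	0.33	0.12	0.80
SA305A.pdb	-0.350	-0.02	0.00	-0.11
EA313K.pdb	0.905	0.05	0.21	0.18
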