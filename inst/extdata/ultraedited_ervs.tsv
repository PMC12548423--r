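# Published comparison table of extensively hypermutated ERVs and XRVs:
# raw counts (length, G>A, total mismatches) with the printed derived cells
# (% G>A of mismatches; G>A per 1,000 bp) at their printed precision.
# incons* flags mark printed cells that disagree with their own row's
# counts; such cells are reported, never asserted.
name	length	GA	total	printedPct	decPct	printedPerKb	decPerKb	inconsPct	inconsPerKb
Mtv21	7924	957	1158	82.6	1	120.8	1	FALSE	FALSE
Mtv61	7923	387	997	38.8	1	48.8	1	FALSE	FALSE
Mtv61-3p	3450	280	518	54.1	1	81.2	1	FALSE	FALSE
TguERVl1_I-int	5486	392	475	82.53	2	71.5	1	FALSE	FALSE
TguLTRK1_1	6173	353	440	80.23	2	57.2	1	FALSE	FALSE
MuRRS-int	4657	199	225	88.44	2	42.7	1	FALSE	FALSE
IAPEz-int	6382	198	233	85.34	2	31.0	1	TRUE	FALSE
HERVK-int	5375	148	205	72.2	1	27.5	1	FALSE	FALSE
NICER2_Ra-int	7513	93	100	93	0	12.4	1	FALSE	FALSE
HIV-1_VAU	9330	679	722	94	0	72.8	1	FALSE	FALSE
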