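chrom	length	cen_start	cen_end
chr1	240000000	118000000	122000000
chr2	231000000	90000000	94000000
chr3	223000000	110000000	114000000
chr4	214000000	84000000	88000000
chr5	206000000	101000000	105000000
chr6	197000000	77000000	81000000
chr7	189000000	92000000	96000000
chr8	180000000	70000000	74000000
chr9	171000000	84000000	88000000
chr10	163000000	63000000	67000000
chr11	154000000	75000000	79000000
chr12	146000000	56000000	60000000
chr13	137000000	66000000	70000000
chr14	129000000	50000000	54000000
chr15	120000000	58000000	62000000
chr16	111000000	42000000	46000000
chr17	103000000	50000000	54000000
chr18	94000000	36000000	40000000
chr19	86000000	41000000	45000000
chr20	77000000	29000000	33000000
chr21	69000000	32000000	36000000
chr22	60000000	22000000	26000000
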