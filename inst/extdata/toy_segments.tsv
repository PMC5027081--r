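chrom	start	end	n_probes	seg_mean
1	0	650000	5	0.25
1	650000	910000	2	0.5
2	0	1300000	10	-0.21
3	0	1300000	100	0.0
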