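snp_id	risk_allele_freq	odds_ratio
snp01_synth	0.2471	1.0904
snp02_synth	0.0982	1.0609
snp03_synth	0.6275	1.07
snp04_synth	0.3594	1.0499
snp05_synth	0.1411	1.0787
snp06_synth	0.1873	1.0446
snp07_synth	0.5168	1.0406
snp08_synth	0.7336	1.0677
snp09_synth	0.8464	1.0876
snp10_synth	0.2564	1.0609
snp11_synth	0.7061	1.0715
snp12_synth	0.4834	1.102
snp13_synth	0.6033	1.0421
snp14_synth	0.6821	1.0686
snp15_synth	0.686	1.125
snp16_synth	0.1227	1.0739
snp17_synth	0.1568	1.0815
snp18_synth	0.625	1.1168
snp19_synth	0.5776	1.1068
snp20_synth	0.6215	1.0556
snp21_synth	0.3885	1.0965
snp22_synth	0.1279	1.0657
snp23_synth	0.7818	1.0604
snp24_synth	0.4119	1.0691
snp25_synth	0.162	1.0453
snp26_synth	0.1834	1.0803
snp27_synth	0.8839	1.0384
snp28_synth	0.273	1.0784
snp29_synth	0.7796	1.0241
snp30_synth	0.551	1.0635
snp31_synth	0.336	1.0722
snp32_synth	0.5546	1.0427
snp33_synth	0.462	1.0661
snp34_synth	0.3098	1.0906
snp35_synth	0.665	1.083
snp36_synth	0.8277	1.109
snp37_synth	0.2854	1.0673
snp38_synth	0.8879	1.0606
snp39_synth	0.3563	1.0996
snp40_synth	0.7371	1.0813
snp41_synth	0.1506	1.0512
snp42_synth	0.3309	1.0599
snp43_synth	0.5587	1.1021
snp44_synth	0.8025	1.1196
snp45_synth	0.7038	1.0428
snp46_synth	0.5586	1.0801
snp47_synth	0.2413	1.0308
snp48_synth	0.5363	1.0813
snp49_synth	0.1236	1.0251
snp50_synth	0.4746	1.0457
snp51_synth	0.3562	1.0613
snp52_synth	0.3412	1.0781
snp53_synth	0.6055	1.0307
snp54_synth	0.8817	1.0925
snp55_synth	0.3306	1.0624
snp56_synth	0.1931	1.0266
snp57_synth	0.3326	1.0519
snp58_synth	0.2094	1.0505
snp59_synth	0.5687	1.0401
snp60_synth	0.0849	1.0534
snp61_synth	0.2237	1.0734
snp62_synth	0.5732	1.1008
snp63_synth	0.2573	1.0852
snp64_synth	0.603	1.0637
snp65_synth	0.4471	1.0553
snp66_synth	0.8065	1.0408
snp67_synth	0.431	1.0311
snp68_synth	0.2561	1.0647
snp69_synth	0.4173	1.0081
snp70_synth	0.2904	1.0746
snp71_synth	0.6239	1.0558
snp72_synth	0.1795	1.0555
snp73_synth	0.2734	1.0805
snp74_synth	0.8538	1.0791
snp75_synth	0.3463	1.0517
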