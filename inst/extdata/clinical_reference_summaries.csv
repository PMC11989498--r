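disease,feature,label,n,mean,ci_low,ci_high
kidney,contrast,50-60,14,743.31,676.68,809.94
kidney,contrast,60-80,23,582.93,535.89,629.97
kidney,contrast,>=80,15,328.70,269.90,387.51
kidney,correlation,50-60,14,0.0151,-0.0032,0.0126
kidney,correlation,60-80,23,0.0041,-0.0057,0.0140
kidney,correlation,>=80,15,0.0050,-0.0042,0.0008
kidney,energy,50-60,14,0.000288,0.000253,0.000324
kidney,energy,60-80,23,0.000351,0.000308,0.000393
kidney,energy,>=80,15,0.000615,0.000470,0.000761
kidney,homogeneity,50-60,14,0.1054,0.1010,0.1099
kidney,homogeneity,60-80,23,0.1121,0.1072,0.1171
kidney,homogeneity,>=80,15,0.1376,0.1283,0.1468
gallbladder,contrast,50-60,10,1208.24,999.17,1417.32
gallbladder,contrast,60-80,21,258.93,194.45,323.41
gallbladder,contrast,>=80,35,79.74,69.09,90.38
gallbladder,correlation,50-60,10,0.0044,-0.0010,0.0188
gallbladder,correlation,60-80,21,0.0102,0.0034,0.0170
gallbladder,correlation,>=80,35,0.0048,-0.0007,0.0103
gallbladder,energy,50-60,10,0.000054,0.000040,0.000068
gallbladder,energy,60-80,21,0.001020,0.000750,0.001290
gallbladder,energy,>=80,35,0.002925,-0.002616,0.003233
gallbladder,homogeneity,50-60,10,0.1288,0.1162,0.1413
gallbladder,homogeneity,60-80,21,0.1573,0.1427,0.1719
gallbladder,homogeneity,>=80,35,0.2188,0.2098,0.2277
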