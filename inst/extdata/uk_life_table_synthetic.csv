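sex,age,m
man,40,0.0013428918
man,41,0.0014529364
man,42,0.0015745929
man,43,0.0017090864
man,44,0.0018577715
man,45,0.0020221457
man,46,0.0022038644
man,47,0.0024047579
man,48,0.0026268494
man,49,0.0028723757
man,50,0.0031438097
man,51,0.0034438851
man,52,0.003775624
man,53,0.0041423677
man,54,0.0045478097
man,55,0.0049960334
man,56,0.0054915532
man,57,0.0060393596
man,58,0.0066449699
man,59,0.0073144835
man,60,0.0080546433
man,61,0.0088729039
man,62,0.0097775064
man,63,0.010777561
man,64,0.011883141
man,65,0.01310538
man,66,0.014456588
man,67,0.015950375
man,68,0.017601783
man,69,0.019427446
man,70,0.021445752
man,71,0.023677026
man,72,0.026143741
man,73,0.028870742
man,74,0.031885492
man,75,0.035218355
man,76,0.038902897
man,77,0.042976229
man,78,0.047479373
man,79,0.052457683
man,80,0.057961299
man,81,0.06404565
man,82,0.070772014
man,83,0.078208136
man,84,0.086428908
man,85,0.095517127
man,86,0.10556432
man,87,0.11667169
man,88,0.12895109
man,89,0.14252619
man,90,0.15753373
man,91,0.17412484
man,92,0.19246663
man,93,0.21274382
man,94,0.23516064
man,95,0.25994285
man,96,0.28734005
man,97,0.31762817
man,98,0.35111226
man,99,0.38812954
man,100,0.42905285
woman,40,0.00087048883
woman,41,0.00093530923
woman,42,0.0010074947
woman,43,0.0010878821
woman,44,0.0011774033
woman,45,0.0012770961
woman,46,0.0013881162
woman,47,0.0015117508
woman,48,0.001649433
woman,49,0.0018027591
woman,50,0.0019735064
woman,51,0.0021636545
woman,52,0.0023754077
woman,53,0.0026112209
woman,54,0.0028738278
woman,55,0.0031662727
woman,56,0.0034919459
woman,57,0.003854623
woman,58,0.0042585084
woman,59,0.0047082843
woman,60,0.0052091649
woman,61,0.0057669569
woman,62,0.0063881266
woman,63,0.0070798751
woman,64,0.007850222
woman,65,0.0087080976
woman,66,0.0096634473
woman,67,0.010727346
woman,68,0.011912128
woman,69,0.013231528
woman,70,0.014700841
woman,71,0.016337102
woman,72,0.018159279
woman,73,0.020188496
woman,74,0.022448278
woman,75,0.024964822
woman,76,0.027767302
woman,77,0.030888208
woman,78,0.034363719
woman,79,0.038234126
woman,80,0.042544299
woman,81,0.047344205
woman,82,0.052689488
woman,83,0.058642116
woman,84,0.065271097
woman,85,0.07265328
woman,86,0.080874246
woman,87,0.090029299
woman,88,0.10022457
woman,89,0.11157826
woman,90,0.12422198
woman,91,0.13830231
woman,92,0.15398249
woman,93,0.17144429
woman,94,0.19089015
woman,95,0.21254549
woman,96,0.23666137
woman,97,0.26351735
woman,98,0.29342478
woman,99,0.32673037
woman,100,0.36382023
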