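genotype,root_id,root_type,zone,slope_per_mm,correlation,significant,n_cells,end_um
wild_type,A10,A,DZ,0.8,0.12,FALSE,132,855
wild_type,A10,A,EZ,59.5,0.88,TRUE,67,1494
wild_type,A10,A,MZ,49.6,0.78,TRUE,68,2990
wild_type,A31,A,DZ,-6,-0.42,TRUE,78,676
wild_type,A31,A,EZ,50.5,0.9,TRUE,95,1368
wild_type,A31,A,MZ,65.9,0.73,TRUE,70,3126
wild_type,A9,A,DZ,-5.3,-0.35,TRUE,94,587
wild_type,A9,A,EZ,42.4,0.91,TRUE,61,1219
wild_type,A9,A,MZ,43.1,0.76,TRUE,67,3557
wild_type,A8,A,DZ,-3.2,-0.36,FALSE,17,553
wild_type,A8,A,EZ,59.2,0.83,TRUE,34,1100
wild_type,A8,A,MZ,49.4,0.77,TRUE,37,2459
wild_type,A13,A,DZ,-3.6,-0.24,TRUE,109,510
wild_type,A13,A,EZ,90.9,0.87,TRUE,76,973
wild_type,A13,A,MZ,30.1,0.35,TRUE,53,2582
wild_type,B33,B,DZ,-0.2,-0.01,FALSE,103,439
wild_type,B33,B,EZ,201.8,0.82,TRUE,36,672
wild_type,B33,B,MZ,15.1,0.21,FALSE,59,2198
wild_type,B32,B,DZ,-16,-0.53,TRUE,110,411
wild_type,B32,B,EZ,116.3,0.81,TRUE,48,716
wild_type,B32,B,MZ,35.2,0.44,TRUE,39,1852
wild_type,B19,B,DZ,11.6,0.42,TRUE,30,366
wild_type,B19,B,EZ,118.8,0.85,TRUE,31,600
wild_type,B19,B,MZ,21.2,0.36,TRUE,36,2283
wild_type,A11,A,DZ,-6.3,-0.25,FALSE,55,328
wild_type,A11,A,EZ,83,0.9,TRUE,77,655
wild_type,A11,A,MZ,74.6,0.72,TRUE,50,1898
wild_type,A12,A,DZ,1.3,0.05,FALSE,49,320
wild_type,A12,A,EZ,102.5,0.91,TRUE,44,722
wild_type,A12,A,MZ,13.3,0.33,TRUE,77,2967
wild_type,B34,B,DZ,-9.6,-0.4,TRUE,27,278
wild_type,B34,B,EZ,140.1,0.72,TRUE,57,461
wild_type,B34,B,MZ,27.6,0.55,TRUE,68,2182
wild_type,B20,B,DZ,1,0.02,FALSE,48,232
wild_type,B20,B,EZ,201.4,0.88,TRUE,52,574
wild_type,B20,B,MZ,15.9,0.44,TRUE,34,2775
wild_type,B35,B,DZ,-22.1,-0.32,TRUE,44,215
wild_type,B35,B,EZ,183.3,0.76,TRUE,44,388
wild_type,B35,B,MZ,3.2,0.09,FALSE,79,2771
wild_type,C25,C,EZ,159,0.75,TRUE,18,144
wild_type,C25,C,MZ,30.6,0.82,TRUE,110,1961
wild_type,C28,C,EZ,108.6,0.53,TRUE,40,115
wild_type,C28,C,MZ,9.4,0.26,TRUE,111,1424
wild_type,C26,C,MZ,28.1,0.82,TRUE,133,2115
wild_type,C27,C,MZ,22.7,0.72,TRUE,136,2172
wild_type,C30,C,MZ,27.6,0.69,TRUE,170,2214
rtcs,A3,A,DZ,11.2,0.34,TRUE,67,617
rtcs,A3,A,EZ,83.4,0.81,TRUE,29,1385
rtcs,A3,A,MZ,7.7,0.05,FALSE,16,2277
rtcs,A1,A,DZ,8.3,0.36,TRUE,92,535
rtcs,A1,A,EZ,59.6,0.88,TRUE,60,1185
rtcs,A1,A,MZ,24.5,0.34,TRUE,62,3407
rtcs,A'36,A',DZ,2.3,0.15,FALSE,116,506
rtcs,A'36,A',EZ,92.2,0.93,TRUE,39,1146
rtcs,A'36,A',MZ,25.5,0.3,FALSE,22,1998
rtcs,A2,A,DZ,27.9,0.64,TRUE,68,323
rtcs,A2,A,EZ,157.5,0.86,TRUE,29,744
rtcs,A2,A,MZ,10.1,0.17,FALSE,35,2257
rtcs,A'37,A',DZ,20.4,0.63,TRUE,42,313
rtcs,A'37,A',EZ,82.2,0.84,TRUE,51,707
rtcs,A'37,A',MZ,31.2,0.47,TRUE,40,1514
rtcs,A'38,A',DZ,9.7,0.51,TRUE,46,272
rtcs,A'38,A',EZ,111.7,0.82,TRUE,41,505
rtcs,A'38,A',MZ,28.7,0.49,TRUE,47,1621
rtcs,A'39,A',EZ,66,0.84,TRUE,37,980
rtcs,A'39,A',MZ,23.5,0.23,FALSE,27,1844
rtcs,B15,B,EZ,139.5,0.96,TRUE,30,520
rtcs,B15,B,MZ,-9.5,-0.18,FALSE,22,1493
rum1,A5,A,DZ,-3.3,-0.28,TRUE,157,787
rum1,A5,A,EZ,65,0.96,TRUE,73,2360
rum1,A5,A,MZ,21.1,0.22,FALSE,29,4090
rum1,A7,A,DZ,3,0.15,FALSE,71,456
rum1,A7,A,EZ,62,0.85,TRUE,55,1123
rum1,A7,A,MZ,41,0.58,TRUE,13,2109
rum1,A'41,A',DZ,-6,-0.17,FALSE,75,452
rum1,A'41,A',EZ,75,0.84,TRUE,61,1246
rum1,A'41,A',MZ,16.9,0.18,FALSE,16,2329
rum1,A4,A,DZ,0,0,FALSE,101,399
rum1,A4,A,EZ,42.3,0.8,TRUE,87,1068
rum1,A4,A,MZ,6.5,0.08,FALSE,46,1870
rum1,A'40,A',DZ,19.5,0.43,TRUE,122,385
rum1,A'40,A',EZ,139.9,0.71,TRUE,41,689
rum1,A'40,A',MZ,13,0.2,FALSE,52,2235
rum1,A6,A,DZ,-14.7,-0.57,TRUE,68,371
rum1,A6,A,EZ,43.1,0.83,TRUE,67,958
rum1,A6,A,MZ,73.7,0.64,TRUE,31,2139
rum1,A'42,A',DZ,26.7,0.57,TRUE,73,295
rum1,A'42,A',EZ,145.3,0.93,TRUE,33,627
rum1,A'42,A',MZ,2.4,0.06,FALSE,55,2325
rum1,C22,C,EZ,11.6,0.61,TRUE,73,1510
rum1,C22,C,MZ,14.4,0.34,TRUE,38,2820
rum1,C24,C,EZ,9.8,0.38,TRUE,62,540
rum1,C24,C,MZ,13.5,0.67,TRUE,81,3247
rum1,C23,C,EZ,85.2,0.85,TRUE,39,732
rum1,C23,C,MZ,22.6,0.64,TRUE,48,2008
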