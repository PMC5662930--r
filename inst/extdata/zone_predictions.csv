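genotype,root_id,root_type,zone,pred_start_um,pred_end_um,end_um
wild_type,A10,A,DZ,5.4,6,855
wild_type,A10,A,EZ,7.3,45.4,1494
wild_type,A10,A,MZ,53.3,127.6,2990
wild_type,A31,A,DZ,9.3,5.7,676
wild_type,A31,A,EZ,6.1,41,1368
wild_type,A31,A,MZ,59.3,175.2,3126
wild_type,A9,A,DZ,7.8,5.1,587
wild_type,A9,A,EZ,6.7,33.5,1219
wild_type,A9,A,MZ,52.6,153.4,3557
wild_type,A8,A,DZ,7.7,6.7,553
wild_type,A8,A,EZ,7.6,40,1100
wild_type,A8,A,MZ,51.7,118.8,2459
wild_type,A13,A,DZ,7.3,5.4,510
wild_type,A13,A,EZ,6.5,48.6,973
wild_type,A13,A,MZ,88.6,137,2582
wild_type,B33,B,DZ,6.4,6.3,439
wild_type,B33,B,EZ,9.6,56.6,672
wild_type,B33,B,MZ,83.9,107.1,2198
wild_type,B32,B,DZ,9.3,3.6,411
wild_type,B32,B,EZ,10,45.5,716
wild_type,B32,B,MZ,73.8,113.8,1852
wild_type,B19,B,DZ,6.5,8.9,366
wild_type,B19,B,EZ,11.2,39,600
wild_type,B19,B,MZ,87.2,122.9,2283
wild_type,A11,A,DZ,7.3,5.5,328
wild_type,A11,A,EZ,5.1,32.3,655
wild_type,A11,A,MZ,54.9,147.6,1898
wild_type,A12,A,DZ,5.9,6.2,320
wild_type,A12,A,EZ,7.1,48.3,722
wild_type,A12,A,MZ,69.1,98.9,2967
wild_type,B34,B,DZ,6.4,4.9,278
wild_type,B34,B,EZ,4.8,30.5,461
wild_type,B34,B,MZ,62.4,109.9,2182
wild_type,B20,B,DZ,11.3,11.5,232
wild_type,B20,B,EZ,11.6,80.4,574
wild_type,B20,B,MZ,102.2,137.2,2775
wild_type,B35,B,DZ,9.2,5.1,215
wild_type,B35,B,EZ,9,40.7,388
wild_type,B35,B,MZ,63.5,71,2771
wild_type,C25,C,EZ,5.2,25.7,144
wild_type,C25,C,MZ,24.6,80.3,1961
wild_type,C28,C,EZ,6.3,16.7,115
wild_type,C28,C,MZ,29.2,41.4,1424
wild_type,C26,C,MZ,20.3,79.2,2115
wild_type,C27,C,MZ,28.5,77.2,2172
wild_type,C30,C,MZ,28.7,89,2214
rtcs,A3,A,DZ,11.9,18.3,617
rtcs,A3,A,EZ,26,90.1,1385
rtcs,A3,A,MZ,101.5,108.4,2277
rtcs,A1,A,DZ,7.6,12,535
rtcs,A1,A,EZ,15.9,54.6,1185
rtcs,A1,A,MZ,77.2,131.6,3407
rtcs,A'36,A',DZ,7.5,8.6,506
rtcs,A'36,A',EZ,10.4,69.4,1146
rtcs,A'36,A',MZ,68.6,90.3,1998
rtcs,A2,A,DZ,5.6,14.6,323
rtcs,A2,A,EZ,17.5,83.8,744
rtcs,A2,A,MZ,81.9,97.2,2257
rtcs,A'37,A',DZ,5.6,9.1,313
rtcs,A'37,A',EZ,10,42.4,707
rtcs,A'37,A',MZ,50.4,75.5,1514
rtcs,A'38,A',DZ,6.3,9,272
rtcs,A'38,A',EZ,4.8,30.8,505
rtcs,A'38,A',MZ,42.9,75,1621
rtcs,A'39,A',EZ,11.1,59.7,980
rtcs,A'39,A',MZ,54.4,74.7,1844
rtcs,B15,B,EZ,8.9,79.3,520
rtcs,B15,B,MZ,68.5,59.2,1493
rum1,A5,A,DZ,10.2,7.7,787
rum1,A5,A,EZ,9.8,112,2360
rum1,A5,A,MZ,104.5,140.9,4090
rum1,A7,A,DZ,6.7,7.8,456
rum1,A7,A,EZ,7.4,48.8,1123
rum1,A7,A,MZ,71.7,112.2,2109
rum1,A'41,A',DZ,13.7,11,452
rum1,A'41,A',EZ,12.5,72.1,1246
rum1,A'41,A',MZ,59.6,78,2329
rum1,A4,A,DZ,8.9,8.9,399
rum1,A4,A,EZ,10.9,39.2,1068
rum1,A4,A,MZ,49.8,55,1870
rum1,A'40,A',DZ,9.9,17.4,385
rum1,A'40,A',EZ,18.8,61.3,689
rum1,A'40,A',MZ,72.4,92.6,2235
rum1,A6,A,DZ,12,6.6,371
rum1,A6,A,EZ,6.4,31.6,958
rum1,A6,A,MZ,39.5,126.5,2139
rum1,A'42,A',DZ,7.3,15.2,295
rum1,A'42,A',EZ,12.1,60.3,627
rum1,A'42,A',MZ,61.6,65.7,2325
rum1,C22,C,EZ,13.2,29.2,1510
rum1,C22,C,MZ,55.2,74.1,2820
rum1,C24,C,EZ,15.4,20.7,540
rum1,C24,C,MZ,23.9,60.6,3247
rum1,C23,C,EZ,8,53.5,732
rum1,C23,C,MZ,39.8,68.7,2008
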