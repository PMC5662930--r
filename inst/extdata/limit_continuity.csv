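genotype,root_id,root_type,limit,limit_um,rootward_lo,rootward_hi,shootward_lo,shootward_hi
wild_type,A10,A,DZ-EZ,855,5.5,6.5,5,9.7
wild_type,A10,A,EZ-MZ,1494,41.8,48.9,45.7,61
wild_type,A31,A,DZ-EZ,676,4.8,6.7,4.2,8
wild_type,A31,A,EZ-MZ,1368,38.9,43.2,47.7,70.9
wild_type,A9,A,DZ-EZ,587,4.2,6,5,8.3
wild_type,A9,A,EZ-MZ,1219,31.5,35.4,40.2,65
wild_type,A8,A,DZ-EZ,553,6.1,7.2,2.4,12.8
wild_type,A8,A,EZ-MZ,1100,36.4,43.6,42.7,60.7
wild_type,A13,A,DZ-EZ,510,4.7,6.2,3.9,9.2
wild_type,A13,A,EZ-MZ,973,45.1,52.2,69.2,108
wild_type,B33,B,DZ-EZ,439,5.5,7,4.4,14.8
wild_type,B33,B,EZ-MZ,672,49.2,64,68.6,99.3
wild_type,B32,B,DZ-EZ,411,2.5,4.7,6.1,13.8
wild_type,B32,B,EZ-MZ,716,40.7,50.2,60.6,87.1
wild_type,B19,B,DZ-EZ,366,7.8,9.9,7.7,14.6
wild_type,B19,B,EZ-MZ,600,34.9,43,66.6,107.8
wild_type,A11,A,DZ-EZ,328,4.3,6.7,3.6,6.6
wild_type,A11,A,EZ-MZ,655,30.3,34.2,44.1,65.7
wild_type,A12,A,DZ-EZ,320,5.3,7.1,4.5,9.7
wild_type,A12,A,EZ-MZ,722,44.2,52.4,59,79.2
wild_type,B34,B,DZ-EZ,278,4.1,5.7,1.4,8.3
wild_type,B34,B,EZ-MZ,461,26.5,34.5,52.7,72.2
wild_type,B20,B,DZ-EZ,232,10,13,6.5,16.6
wild_type,B20,B,EZ-MZ,574,73.5,87.4,88.5,115.9
wild_type,B35,B,DZ-EZ,215,3.3,7,4.8,13.2
wild_type,B35,B,EZ-MZ,388,35.5,45.9,55.1,71.9
wild_type,C25,C,EZ-MZ,144,18.2,33.1,20.9,28.4
wild_type,C28,C,EZ-MZ,115,13.9,19.5,25,33.4
rtcs,A3,A,DZ-EZ,617,15.7,20.9,17.7,34.4
rtcs,A3,A,EZ-MZ,1385,77.7,102.4,63.7,139.4
rtcs,A1,A,DZ-EZ,535,10.5,13.6,13.3,18.5
rtcs,A1,A,EZ-MZ,1185,50.8,58.4,57.1,97.3
rtcs,A'36,A',DZ-EZ,506,7.8,9.4,7.1,13.8
rtcs,A'36,A',EZ-MZ,1146,63.8,75,51.1,86.2
rtcs,A2,A,DZ-EZ,323,13,16.2,10.4,24.7
rtcs,A2,A,EZ-MZ,744,73.4,94.3,64.3,99.5
rtcs,A'37,A',DZ-EZ,313,8.3,9.9,7.1,12.8
rtcs,A'37,A',EZ-MZ,707,38.2,46.5,41.6,59.2
rtcs,A'38,A',DZ-EZ,272,8.3,9.6,2.7,6.8
rtcs,A'38,A',EZ-MZ,505,26.3,35.3,34.2,51.7
rtcs,A'39,A',EZ-MZ,980,53.1,66.3,34.3,74.4
rtcs,B15,B,EZ-MZ,520,73.7,85,54.9,82
rum1,A5,A,DZ-EZ,787,6.9,8.5,6.6,12.9
rum1,A5,A,EZ-MZ,2360,106.5,117.6,69,140
rum1,A7,A,DZ-EZ,456,6.9,8.6,4.3,10.5
rum1,A7,A,EZ-MZ,1123,43.7,53.8,51.7,91.7
rum1,A'41,A',DZ-EZ,452,9.1,12.9,8.4,16.6
rum1,A'41,A',EZ-MZ,1246,64.9,79.2,27.6,91.6
rum1,A4,A,DZ-EZ,399,8.1,9.8,8.7,13.1
rum1,A4,A,EZ-MZ,1068,36.1,42.3,38.5,61
rum1,A'40,A',DZ-EZ,385,15.7,19.1,12.2,25.4
rum1,A'40,A',EZ-MZ,689,52.1,70.6,58.4,86.4
rum1,A6,A,DZ-EZ,371,5.6,7.6,4.4,8.4
rum1,A6,A,EZ-MZ,958,28.8,34.5,20.1,59
rum1,A'42,A',DZ-EZ,295,13.5,16.9,8.9,15.3
rum1,A'42,A',EZ-MZ,627,55.4,65.3,51.1,72.1
rum1,C22,C,EZ-MZ,1510,26.6,31.9,45.5,65
rum1,C24,C,EZ-MZ,540,18.7,22.7,19.5,28.4
rum1,C23,C,EZ-MZ,732,47.1,59.8,34.1,45.5
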