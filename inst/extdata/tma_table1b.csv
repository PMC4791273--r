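id,sex,age,group,ploidy,T,N,M,G,UICC,survival_months,status,ip
N01,m,59,normal,none,,,,,,,,0.1022
N02,m,58,normal,none,,,,,,,,0.0881
N03,w,78,normal,none,,,,,,,,0.0052
N04,m,57,normal,none,,,,,,,,0.0459
N05,w,52,normal,none,,,,,,,,0.0018
N06,m,74,normal,none,,,,,,,,0.0099
N07,m,47,normal,none,,,,,,,,0.1199
N08,w,51,normal,none,,,,,,,,0.0330
N09,m,66,normal,none,,,,,,,,0.0038
N10,w,74,normal,none,,,,,,,,0.1991
D01,m,59,tumor,diploid,3,0,0,2,1,90.0,alive,0.0020
D02,w,61,tumor,diploid,4,0,0,2,1,154.0,alive,0.2673
D03,w,75,tumor,diploid,3,0,0,2,1,57.6,dead,0.2191
D04,m,58,tumor,diploid,3,0,0,2,1,40.8,dead,0.5336
D05,w,78,tumor,diploid,4,0,0,2,1,50.4,dead,0.4410
D06,m,77,tumor,diploid,2,1,0,3,2,114.0,alive,0.2467
D07,m,57,tumor,diploid,3,1,0,2,2,64.8,alive,0.4448
D08,w,52,tumor,diploid,2,1,0,2,2,142.0,alive,0.2371
D09,w,73,tumor,diploid,4,1,0,3,2,18.0,dead,0.2715
A01,m,74,tumor,aneuploid,3,0,0,2,1,142.0,alive,0.3007
A02,m,47,tumor,aneuploid,3,0,0,3,1,133.0,alive,0.1592
A03,w,74,tumor,aneuploid,3,0,0,2,1,176.0,alive,0.3615
A04,w,72,tumor,aneuploid,3,0,0,2,1,27.6,dead,0.7899
A05,m,64,tumor,aneuploid,3,0,0,3,1,55.2,dead,0.4529
A06,w,51,tumor,aneuploid,3,1,0,2,2,109.0,alive,0.2003
A07,m,66,tumor,aneuploid,4,1,0,3,2,145.0,alive,0.0780
A08,w,74,tumor,aneuploid,3,1,0,3,2,10.8,dead,0.5090
A09,w,63,tumor,aneuploid,3,1,0,2,2,27.6,dead,0.6380
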