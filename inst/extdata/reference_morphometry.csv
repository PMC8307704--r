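day,group,variable,mean,sd
7,CONT,D,527.2,279.3
7,CONT,DPA,134280.2,60364.62
7,CONT,EPI,50.9,13.1
7,CONT,L,1909.8,901.6
7,CONT,N,1434.4,196.7
7,CONT,NEO,83.6,23.4
7,CONT,S,1533.2,791.5
7,CONT,T,915.5,298.8
7,CONT,H,1604.5,980.1
7,CONT,B,189079.1,127604.5
7,CONT,SCI,0.21,0.15
7,CONT,DCI,0.63,0.15
7,CONT,WSI,0.35,0.22
7,CONT,GHI,0.49,0.32
7,CONT,GCI,0.85,0.21
7,CONT,RHI,-2.76,0.61
7,CONT,MRI,2.35,0.67
7,CONT,GRI,-2.09,0.44
7,gNAC,D,627.5,193.2
7,gNAC,DPA,180923.8,190501.1
7,gNAC,EPI,43.3,11.5
7,gNAC,L,1932.1,649.9
7,gNAC,N,1427.2,169.5
7,gNAC,NEO,98.8,24.4
7,gNAC,S,1312.6,630.3
7,gNAC,T,802.9,270.5
7,gNAC,H,1448.4,1152.6
7,gNAC,B,155889.7,140034.4
7,gNAC,SCI,0.34,0.15
7,gNAC,DCI,0.55,0.13
7,gNAC,WSI,0.44,0.14
7,gNAC,GHI,0.45,0.31
7,gNAC,GCI,0.90,0.21
7,gNAC,RHI,0.09,0.71
7,gNAC,MRI,0.17,0.74
7,gNAC,GRI,0.13,0.61
7,NAC30,D,558.3,251.7
7,NAC30,DPA,353591.2,314148.8
7,NAC30,EPI,42.4,12.2
7,NAC30,L,1471.0,810.9
7,NAC30,N,1459.5,65.5
7,NAC30,NEO,102.3,43.85
7,NAC30,S,820.3,670.0
7,NAC30,T,794.5,145.9
7,NAC30,H,1731.1,762.5
7,NAC30,B,222271.6,196386.6
7,NAC30,SCI,0.46,0.18
7,NAC30,DCI,0.62,0.16
7,NAC30,WSI,0.45,0.12
7,NAC30,GHI,0.63,0.39
7,NAC30,GCI,1.08,0.27
7,NAC30,RHI,-0.07,0.47
7,NAC30,MRI,-0.17,1.03
7,NAC30,GRI,-0.12,0.51
14,CONT,D,313.0,96.8
14,CONT,DPA,405838.2,226281.4
14,CONT,EPI,44.4,10.2
14,CONT,L,1272.9,484.5
14,CONT,N,1404.1,187.8
14,CONT,NEO,110.1,28.9
14,CONT,S,1150.8,541.2
14,CONT,T,1289,192.6
14,CONT,H,1890.3,1082.3
14,CONT,B,652444.9,293520.0
14,CONT,SCI,0.11,0.21
14,CONT,DCI,0.77,0.06
14,CONT,WSI,0.09,0.14
14,CONT,GHI,0.80,0.22
14,CONT,GCI,0.89,0.22
14,CONT,RHI,-0.17,0.67
14,CONT,MRI,-2.45,1.55
14,CONT,GRI,-1.31,1.06
14,gNAC,D,375.8,191.8
14,gNAC,DPA,550007.5,508475.6
14,gNAC,EPI,46.0,14.3
14,gNAC,L,1382.7,570.5
14,gNAC,N,1496.0,393.1
14,gNAC,NEO,114.2,33.2
14,gNAC,S,1268.9,676.7
14,gNAC,T,1484.3,381.8
14,gNAC,H,1679.2,1134.4
14,gNAC,B,622769.1,387104.4
14,gNAC,SCI,0.11,0.25
14,gNAC,DCI,0.77,0.07
14,gNAC,WSI,0.04,0.17
14,gNAC,GHI,0.84,0.30
14,gNAC,GCI,0.88,0.28
14,gNAC,RHI,-0.04,0.70
14,gNAC,MRI,-2.29,2.04
14,gNAC,GRI,-1.17,1.02
60,CONT,D,157.2,98.2
60,CONT,DPA,906748.8,572360.8
60,CONT,EPI,28.1,6.04
60,CONT,L,793.99,456.6
60,CONT,N,1680.7,369.3
60,CONT,NEO,38.1,7.82
60,CONT,S,696.69,403.1
60,CONT,T,1650.1,435.3
60,CONT,H,542.48,248.6
60,CONT,B,619803.1,407497.9
60,CONT,SCI,0.12,0.08
60,CONT,DCI,0.90,0.06
60,CONT,WSI,0.01,0.11
60,CONT,GHI,1.01,0.18
60,CONT,GCI,1.02,0.10
60,CONT,RHI,0.66,0.15
60,CONT,MRI,-2.27,2.15
60,CONT,GRI,-0.80,1.11
60,gNAC,D,143.4,88.0
60,gNAC,DPA,743650.1,336697.1
60,gNAC,EPI,28.4,5.21
60,gNAC,L,919.22,815.1
60,gNAC,N,1625.0,246.4
60,gNAC,NEO,37.3,12.9
60,gNAC,S,836.99,776.4
60,gNAC,T,1542.3,275.6
60,gNAC,H,736.08,705.2
60,gNAC,B,645390.3,409208.7
60,gNAC,SCI,0.10,0.07
60,gNAC,DCI,0.91,0.05
60,gNAC,WSI,0.05,0.10
60,gNAC,GHI,0.96,0.15
60,gNAC,GCI,1.01,0.09
60,gNAC,RHI,0.54,0.43
60,gNAC,MRI,-2.41,2.16
60,gNAC,GRI,-0.93,1.22
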