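class,strain,n_species,chow_mean,chow_sem,hfd_mean,hfd_sem,n_down,n_up
CER,C57BL/6,9,0.07,0.01,0.07,0.01,0,0
CER,129X1,9,0.05,0.01,0.06,0.01,0,0
CER,BALB/c,9,0.07,0.01,0.07,0.01,0,0
CER,DBA/2,9,0.07,0.01,0.07,0.01,0,0
CER,FVB/N,9,0.05,0.01,0.06,0.01,0,0
SM,C57BL/6,27,0.28,0.03,0.28,0.03,1,3
SM,129X1,27,0.27,0.01,0.30,0.02,1,5
SM,BALB/c,27,0.31,0.02,0.31,0.01,1,1
SM,DBA/2,27,0.34,0.03,0.29,0.01,3,2
SM,FVB/N,27,0.32,0.01,0.30,0.01,2,0
DAG,C57BL/6,14,1.55,0.27,1.80,0.42,0,0
DAG,129X1,14,1.91,0.24,1.72,0.13,0,0
DAG,BALB/c,14,2.12,0.31,1.92,0.22,0,0
DAG,DBA/2,14,2.07,0.35,1.88,0.15,0,0
DAG,FVB/N,14,1.43,0.04,1.79,0.11,0,0
TAG,C57BL/6,32,7.81,1.70,12.10,2.82,0,4
TAG,129X1,32,12.64,1.72,31.61,1.78,0,13
TAG,BALB/c,32,13.31,1.27,23.48,2.28,0,6
TAG,DBA/2,32,17.57,2.04,45.16,6.08,0,12
TAG,FVB/N,32,12.90,0.67,21.07,1.58,0,4
CE,C57BL/6,9,0.08,0.03,0.04,0.01,0,0
CE,129X1,9,0.04,0.01,0.14,0.02,0,3
CE,BALB/c,9,0.02,0.01,0.06,0.01,0,1
CE,DBA/2,9,0.07,0.03,0.05,0.01,0,0
CE,FVB/N,9,0.06,0.02,0.10,0.001,0,0
PL,C57BL/6,96,14.75,1.49,14.12,0.35,15,15
PL,129X1,96,12.64,0.59,13.96,0.41,6,18
PL,BALB/c,96,14.94,1.23,14.75,0.28,15,12
PL,DBA/2,96,15.97,0.63,15.46,0.49,15,11
PL,FVB/N,96,13.02,0.35,13.73,0.35,7,15
PC,C57BL/6,35,11.27,1.13,10.84,0.26,8,7
PC,129X1,35,9.97,0.58,10.38,0.32,5,7
PC,BALB/c,35,12.08,0.97,11.38,0.24,11,6
PC,DBA/2,35,12.11,0.45,11.61,0.37,7,4
PC,FVB/N,35,9.96,0.18,10.20,0.29,6,5
PC-O,C57BL/6,13,0.28,0.03,0.31,0.01,2,2
PC-O,129X1,13,0.26,0.01,0.31,0.02,0,2
PC-O,BALB/c,13,0.33,0.01,0.34,0.01,2,2
PC-O,DBA/2,13,0.40,0.02,0.37,0.01,2,2
PC-O,FVB/N,13,0.22,0.01,0.27,0.01,1,1
PE,C57BL/6,26,3.15,0.34,2.93,0.13,4,6
PE,129X1,26,2.39,0.08,3.26,0.12,1,5
PE,BALB/c,26,2.55,0.27,3.02,0.07,2,3
PE,DBA/2,26,3.51,0.30,3.46,0.09,4,3
PE,FVB/N,26,2.74,0.16,3.16,0.17,0,6
PE-O,C57BL/6,16,0.53,0.09,0.48,0.03,1,0
PE-O,129X1,16,0.39,0.04,0.70,0.05,0,3
PE-O,BALB/c,16,0.34,0.08,0.51,0.03,0,0
PE-O,DBA/2,16,0.66,0.08,0.57,0.02,2,1
PE-O,FVB/N,16,0.47,0.05,0.57,0.01,0,2
PS,C57BL/6,6,0.33,0.07,0.35,0.01,0,0
PS,129X1,6,0.29,0.01,0.32,0.02,0,1
PS,BALB/c,6,0.30,0.01,0.35,0.01,0,1
PS,DBA/2,6,0.35,0.04,0.40,0.03,0,1
PS,FVB/N,6,0.32,0.02,0.37,0.01,0,1
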