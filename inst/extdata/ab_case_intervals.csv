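participant,outcome,param,lower,upper
1,total,beta11,77.52,79.00
1,total,beta21,81.38,83.49
1,total,es,1.47,5.91
1,adl,beta11,38.68,39.39
1,adl,beta21,41.44,42.38
1,adl,es,2.93,7.67
1,bpsd,beta11,25.84,26.14
1,bpsd,beta21,26.52,27.02
1,bpsd,es,1.46,4.89
1,cog,beta11,12.81,13.21
1,cog,beta21,14.08,14.63
1,cog,es,2.28,6.09
2,total,beta11,64.52,68.70
2,total,beta21,64.88,68.73
2,total,es,-0.83,0.95
2,adl,beta11,37.40,40.61
2,adl,beta21,36.80,39.47
2,adl,es,-1.44,0.56
2,bpsd,beta11,23.48,25.89
2,bpsd,beta21,23.62,25.77
2,bpsd,es,-0.88,0.90
2,cog,beta11,6.43,8.61
2,cog,beta21,7.16,9.26
2,cog,es,-0.56,1.64
3,total,beta11,83.65,87.04
3,total,beta21,82.09,85.73
3,total,es,-1.17,0.33
3,adl,beta11,43.82,47.39
3,adl,beta21,43.05,46.51
3,adl,es,-1.05,0.56
3,bpsd,beta11,24.26,26.97
3,bpsd,beta21,24.20,26.61
3,bpsd,es,-1.14,0.92
3,cog,beta11,12.23,15.72
3,cog,beta21,11.74,14.76
3,cog,es,-1.23,0.60
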