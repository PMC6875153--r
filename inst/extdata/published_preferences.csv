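specimen,CALR,FER,GABRA3,GAD6567,MBP,PARV,SERT,SMI32,SYN,TH,TRANSF,VGLUT1
13-095,B,B,D,B,D,D,C,B,D,B,D,B
14-037,B,B,B,B,B,B,B,B,D,D,B,D
14-051,B,D,B,B,D,D,B,B,D,B,D,B
14-069,B,B,B,B,D,B,B,C,C,C,C,D
15-033,B,B,B,B,B,B,B,B,B,B,B,B
15-035,B,C,D,B,B,D,B,D,B,B,B,C
15-055,B,B,D,B,D,D,B,D,D,D,B,D
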