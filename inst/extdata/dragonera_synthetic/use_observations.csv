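microhabitat,zone,transect
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
OPEN,A,TR1
OPEN,B,TR2
OPEN,A,TR3
OPEN,B,TR4
EPHEDRA,A,TR1
EPHEDRA,B,TR2
EPHEDRA,A,TR3
EPHEDRA,B,TR4
EPHEDRA,A,TR1
EPHEDRA,B,TR2
PISTACIA,A,TR3
PISTACIA,B,TR4
PISTACIA,A,TR1
PISTACIA,B,TR2
PISTACIA,A,TR3
PISTACIA,B,TR4
PISTACIA,A,TR1
PISTACIA,B,TR2
PISTACIA,A,TR3
PISTACIA,B,TR4
PISTACIA,A,TR1
PISTACIA,B,TR2
PISTACIA,A,TR3
PISTACIA,B,TR4
PISTACIA,A,TR1
PISTACIA,B,TR2
PISTACIA,A,TR3
PISTACIA,B,TR4
PISTACIA,A,TR1
PISTACIA,B,TR2
PISTACIA,A,TR3
PISTACIA,B,TR4
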