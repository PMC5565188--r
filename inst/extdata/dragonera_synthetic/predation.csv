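tray_id,microhabitat,zone,set_id,n_exposed,n_surviving,censored
TA_OP_01,OPEN,A,SA01,10,NA,true
TA_OP_02,OPEN,A,SA02,10,0,false
TA_OP_03,OPEN,A,SA03,10,2,false
TA_OP_04,OPEN,A,SA04,10,0,false
TA_OP_05,OPEN,A,SA05,10,0,false
TA_OP_06,OPEN,A,SA06,10,0,false
TA_OP_07,OPEN,A,SA07,10,0,false
TA_OP_08,OPEN,A,SA08,10,0,false
TA_OP_09,OPEN,A,SA09,10,0,false
TA_OP_10,OPEN,A,SA10,10,0,false
TA_EP_01,EPHEDRA,A,SA01,10,0,false
TA_EP_02,EPHEDRA,A,SA02,10,0,false
TA_EP_03,EPHEDRA,A,SA03,10,3,false
TA_EP_04,EPHEDRA,A,SA04,10,0,false
TA_EP_05,EPHEDRA,A,SA05,10,0,false
TA_EP_06,EPHEDRA,A,SA06,10,0,false
TA_EP_07,EPHEDRA,A,SA07,10,0,false
TA_EP_08,EPHEDRA,A,SA08,10,1,false
TA_EP_09,EPHEDRA,A,SA09,10,0,false
TA_EP_10,EPHEDRA,A,SA10,10,0,false
TA_PI_01,PISTACIA,A,SA01,10,1,false
TA_PI_02,PISTACIA,A,SA02,10,0,false
TA_PI_03,PISTACIA,A,SA03,10,0,false
TA_PI_04,PISTACIA,A,SA04,10,0,false
TA_PI_05,PISTACIA,A,SA05,10,1,false
TA_PI_06,PISTACIA,A,SA06,10,0,false
TA_PI_07,PISTACIA,A,SA07,10,2,false
TA_PI_08,PISTACIA,A,SA08,10,0,false
TA_PI_09,PISTACIA,A,SA09,10,0,false
TA_PI_10,PISTACIA,A,SA10,10,1,false
TB_OP_01,OPEN,B,SB01,10,NA,true
TB_OP_02,OPEN,B,SB02,10,NA,true
TB_OP_03,OPEN,B,SB03,10,NA,true
TB_OP_04,OPEN,B,SB04,10,NA,true
TB_OP_05,OPEN,B,SB05,10,0,false
TB_OP_06,OPEN,B,SB06,10,2,false
TB_OP_07,OPEN,B,SB07,10,0,false
TB_OP_08,OPEN,B,SB08,10,0,false
TB_OP_09,OPEN,B,SB09,10,0,false
TB_OP_10,OPEN,B,SB10,10,0,false
TB_EP_01,EPHEDRA,B,SB01,10,NA,true
TB_EP_02,EPHEDRA,B,SB02,10,NA,true
TB_EP_03,EPHEDRA,B,SB03,10,0,false
TB_EP_04,EPHEDRA,B,SB04,10,0,false
TB_EP_05,EPHEDRA,B,SB05,10,0,false
TB_EP_06,EPHEDRA,B,SB06,10,0,false
TB_EP_07,EPHEDRA,B,SB07,10,0,false
TB_EP_08,EPHEDRA,B,SB08,10,0,false
TB_EP_09,EPHEDRA,B,SB09,10,0,false
TB_EP_10,EPHEDRA,B,SB10,10,0,false
TB_PI_01,PISTACIA,B,SB01,10,2,false
TB_PI_02,PISTACIA,B,SB02,10,0,false
TB_PI_03,PISTACIA,B,SB03,10,0,false
TB_PI_04,PISTACIA,B,SB04,10,0,false
TB_PI_05,PISTACIA,B,SB05,10,3,false
TB_PI_06,PISTACIA,B,SB06,10,0,false
TB_PI_07,PISTACIA,B,SB07,10,0,false
TB_PI_08,PISTACIA,B,SB08,10,0,false
TB_PI_09,PISTACIA,B,SB09,10,0,false
TB_PI_10,PISTACIA,B,SB10,10,0,false
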