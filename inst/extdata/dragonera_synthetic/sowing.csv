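station_id,microhabitat,zone,set_id,treatment,n_sown,n_emerged,n_surviving
EA_OP_01,OPEN,A,SA01,DIGESTED,10,4,0
EA_OP_01,OPEN,A,SA01,RED,10,7,3
EA_OP_01,OPEN,A,SA01,YELLOW,10,0,0
EA_OP_02,OPEN,A,SA02,DIGESTED,10,3,0
EA_OP_02,OPEN,A,SA02,RED,10,6,1
EA_OP_02,OPEN,A,SA02,YELLOW,10,3,0
EA_OP_03,OPEN,A,SA03,DIGESTED,10,3,0
EA_OP_03,OPEN,A,SA03,RED,10,4,1
EA_OP_03,OPEN,A,SA03,YELLOW,10,5,0
EA_OP_04,OPEN,A,SA04,DIGESTED,10,7,1
EA_OP_04,OPEN,A,SA04,RED,10,5,0
EA_OP_04,OPEN,A,SA04,YELLOW,10,1,0
EA_OP_05,OPEN,A,SA05,DIGESTED,10,4,0
EA_OP_05,OPEN,A,SA05,RED,10,3,0
EA_OP_05,OPEN,A,SA05,YELLOW,10,3,0
EA_OP_06,OPEN,A,SA06,DIGESTED,10,6,1
EA_OP_06,OPEN,A,SA06,RED,10,6,0
EA_OP_06,OPEN,A,SA06,YELLOW,10,5,0
EA_OP_07,OPEN,A,SA07,DIGESTED,10,4,1
EA_OP_07,OPEN,A,SA07,RED,10,4,3
EA_OP_07,OPEN,A,SA07,YELLOW,10,6,0
EA_OP_08,OPEN,A,SA08,DIGESTED,10,7,2
EA_OP_08,OPEN,A,SA08,RED,10,8,3
EA_OP_08,OPEN,A,SA08,YELLOW,10,4,0
EA_OP_09,OPEN,A,SA09,DIGESTED,10,4,0
EA_OP_09,OPEN,A,SA09,RED,10,7,0
EA_OP_09,OPEN,A,SA09,YELLOW,10,5,0
EA_OP_10,OPEN,A,SA10,DIGESTED,10,4,1
EA_OP_10,OPEN,A,SA10,RED,10,3,0
EA_OP_10,OPEN,A,SA10,YELLOW,10,5,0
EA_EP_01,EPHEDRA,A,SA01,DIGESTED,10,1,0
EA_EP_01,EPHEDRA,A,SA01,RED,10,0,0
EA_EP_01,EPHEDRA,A,SA01,YELLOW,10,0,0
EA_EP_02,EPHEDRA,A,SA02,DIGESTED,10,0,0
EA_EP_02,EPHEDRA,A,SA02,RED,10,2,0
EA_EP_02,EPHEDRA,A,SA02,YELLOW,10,4,0
EA_EP_03,EPHEDRA,A,SA03,DIGESTED,10,4,0
EA_EP_03,EPHEDRA,A,SA03,RED,10,3,0
EA_EP_03,EPHEDRA,A,SA03,YELLOW,10,1,0
EA_EP_04,EPHEDRA,A,SA04,DIGESTED,10,2,0
EA_EP_04,EPHEDRA,A,SA04,RED,10,3,0
EA_EP_04,EPHEDRA,A,SA04,YELLOW,10,1,0
EA_EP_05,EPHEDRA,A,SA05,DIGESTED,10,0,0
EA_EP_05,EPHEDRA,A,SA05,RED,10,2,0
EA_EP_05,EPHEDRA,A,SA05,YELLOW,10,1,0
EA_EP_06,EPHEDRA,A,SA06,DIGESTED,10,0,0
EA_EP_06,EPHEDRA,A,SA06,RED,10,1,0
EA_EP_06,EPHEDRA,A,SA06,YELLOW,10,2,0
EA_EP_07,EPHEDRA,A,SA07,DIGESTED,10,1,0
EA_EP_07,EPHEDRA,A,SA07,RED,10,7,0
EA_EP_07,EPHEDRA,A,SA07,YELLOW,10,0,0
EA_EP_08,EPHEDRA,A,SA08,DIGESTED,10,4,0
EA_EP_08,EPHEDRA,A,SA08,RED,10,2,0
EA_EP_08,EPHEDRA,A,SA08,YELLOW,10,0,0
EA_EP_09,EPHEDRA,A,SA09,DIGESTED,10,4,0
EA_EP_09,EPHEDRA,A,SA09,RED,10,0,0
EA_EP_09,EPHEDRA,A,SA09,YELLOW,10,0,0
EA_EP_10,EPHEDRA,A,SA10,DIGESTED,10,2,0
EA_EP_10,EPHEDRA,A,SA10,RED,10,0,0
EA_EP_10,EPHEDRA,A,SA10,YELLOW,10,0,0
EA_PI_01,PISTACIA,A,SA01,DIGESTED,10,1,0
EA_PI_01,PISTACIA,A,SA01,RED,10,5,0
EA_PI_01,PISTACIA,A,SA01,YELLOW,10,3,0
EA_PI_02,PISTACIA,A,SA02,DIGESTED,10,5,0
EA_PI_02,PISTACIA,A,SA02,RED,10,1,0
EA_PI_02,PISTACIA,A,SA02,YELLOW,10,5,1
EA_PI_03,PISTACIA,A,SA03,DIGESTED,10,3,0
EA_PI_03,PISTACIA,A,SA03,RED,10,4,0
EA_PI_03,PISTACIA,A,SA03,YELLOW,10,0,0
EA_PI_04,PISTACIA,A,SA04,DIGESTED,10,2,0
EA_PI_04,PISTACIA,A,SA04,RED,10,7,0
EA_PI_04,PISTACIA,A,SA04,YELLOW,10,3,0
EA_PI_05,PISTACIA,A,SA05,DIGESTED,10,7,0
EA_PI_05,PISTACIA,A,SA05,RED,10,7,0
EA_PI_05,PISTACIA,A,SA05,YELLOW,10,3,0
EA_PI_06,PISTACIA,A,SA06,DIGESTED,10,10,0
EA_PI_06,PISTACIA,A,SA06,RED,10,5,0
EA_PI_06,PISTACIA,A,SA06,YELLOW,10,0,0
EA_PI_07,PISTACIA,A,SA07,DIGESTED,10,5,0
EA_PI_07,PISTACIA,A,SA07,RED,10,1,0
EA_PI_07,PISTACIA,A,SA07,YELLOW,10,2,0
EA_PI_08,PISTACIA,A,SA08,DIGESTED,10,4,0
EA_PI_08,PISTACIA,A,SA08,RED,10,3,0
EA_PI_08,PISTACIA,A,SA08,YELLOW,10,4,0
EA_PI_09,PISTACIA,A,SA09,DIGESTED,10,3,0
EA_PI_09,PISTACIA,A,SA09,RED,10,6,0
EA_PI_09,PISTACIA,A,SA09,YELLOW,10,5,1
EA_PI_10,PISTACIA,A,SA10,DIGESTED,10,6,1
EA_PI_10,PISTACIA,A,SA10,RED,10,4,0
EA_PI_10,PISTACIA,A,SA10,YELLOW,10,2,0
EB_OP_01,OPEN,B,SB01,DIGESTED,10,8,0
EB_OP_01,OPEN,B,SB01,RED,10,6,1
EB_OP_01,OPEN,B,SB01,YELLOW,10,3,0
EB_OP_02,OPEN,B,SB02,DIGESTED,10,4,0
EB_OP_02,OPEN,B,SB02,RED,10,10,2
EB_OP_02,OPEN,B,SB02,YELLOW,10,4,1
EB_OP_03,OPEN,B,SB03,DIGESTED,10,3,2
EB_OP_03,OPEN,B,SB03,RED,10,9,0
EB_OP_03,OPEN,B,SB03,YELLOW,10,2,1
EB_OP_04,OPEN,B,SB04,DIGESTED,10,8,0
EB_OP_04,OPEN,B,SB04,RED,10,5,1
EB_OP_04,OPEN,B,SB04,YELLOW,10,5,0
EB_OP_05,OPEN,B,SB05,DIGESTED,10,7,3
EB_OP_05,OPEN,B,SB05,RED,10,6,0
EB_OP_05,OPEN,B,SB05,YELLOW,10,2,1
EB_OP_06,OPEN,B,SB06,DIGESTED,10,5,0
EB_OP_06,OPEN,B,SB06,RED,10,6,0
EB_OP_06,OPEN,B,SB06,YELLOW,10,5,1
EB_OP_07,OPEN,B,SB07,DIGESTED,10,4,0
EB_OP_07,OPEN,B,SB07,RED,10,5,0
EB_OP_07,OPEN,B,SB07,YELLOW,10,4,1
EB_OP_08,OPEN,B,SB08,DIGESTED,10,8,0
EB_OP_08,OPEN,B,SB08,RED,10,9,0
EB_OP_08,OPEN,B,SB08,YELLOW,10,3,0
EB_OP_09,OPEN,B,SB09,DIGESTED,10,7,0
EB_OP_09,OPEN,B,SB09,RED,10,6,0
EB_OP_09,OPEN,B,SB09,YELLOW,10,3,0
EB_OP_10,OPEN,B,SB10,DIGESTED,10,7,1
EB_OP_10,OPEN,B,SB10,RED,10,5,2
EB_OP_10,OPEN,B,SB10,YELLOW,10,4,0
EB_EP_01,EPHEDRA,B,SB01,DIGESTED,10,2,0
EB_EP_01,EPHEDRA,B,SB01,RED,10,4,0
EB_EP_01,EPHEDRA,B,SB01,YELLOW,10,0,0
EB_EP_02,EPHEDRA,B,SB02,DIGESTED,10,2,0
EB_EP_02,EPHEDRA,B,SB02,RED,10,6,0
EB_EP_02,EPHEDRA,B,SB02,YELLOW,10,3,0
EB_EP_03,EPHEDRA,B,SB03,DIGESTED,10,0,0
EB_EP_03,EPHEDRA,B,SB03,RED,10,1,0
EB_EP_03,EPHEDRA,B,SB03,YELLOW,10,1,0
EB_EP_04,EPHEDRA,B,SB04,DIGESTED,10,0,0
EB_EP_04,EPHEDRA,B,SB04,RED,10,3,0
EB_EP_04,EPHEDRA,B,SB04,YELLOW,10,1,0
EB_EP_05,EPHEDRA,B,SB05,DIGESTED,10,1,0
EB_EP_05,EPHEDRA,B,SB05,RED,10,3,0
EB_EP_05,EPHEDRA,B,SB05,YELLOW,10,1,0
EB_EP_06,EPHEDRA,B,SB06,DIGESTED,10,2,0
EB_EP_06,EPHEDRA,B,SB06,RED,10,1,0
EB_EP_06,EPHEDRA,B,SB06,YELLOW,10,0,0
EB_EP_07,EPHEDRA,B,SB07,DIGESTED,10,0,0
EB_EP_07,EPHEDRA,B,SB07,RED,10,5,0
EB_EP_07,EPHEDRA,B,SB07,YELLOW,10,0,0
EB_EP_08,EPHEDRA,B,SB08,DIGESTED,10,0,0
EB_EP_08,EPHEDRA,B,SB08,RED,10,0,0
EB_EP_08,EPHEDRA,B,SB08,YELLOW,10,3,0
EB_EP_09,EPHEDRA,B,SB09,DIGESTED,10,0,0
EB_EP_09,EPHEDRA,B,SB09,RED,10,1,0
EB_EP_09,EPHEDRA,B,SB09,YELLOW,10,2,0
EB_EP_10,EPHEDRA,B,SB10,DIGESTED,10,0,0
EB_EP_10,EPHEDRA,B,SB10,RED,10,0,0
EB_EP_10,EPHEDRA,B,SB10,YELLOW,10,1,0
EB_PI_01,PISTACIA,B,SB01,DIGESTED,10,2,0
EB_PI_01,PISTACIA,B,SB01,RED,10,6,1
EB_PI_01,PISTACIA,B,SB01,YELLOW,10,8,0
EB_PI_02,PISTACIA,B,SB02,DIGESTED,10,7,1
EB_PI_02,PISTACIA,B,SB02,RED,10,4,0
EB_PI_02,PISTACIA,B,SB02,YELLOW,10,2,0
EB_PI_03,PISTACIA,B,SB03,DIGESTED,10,3,1
EB_PI_03,PISTACIA,B,SB03,RED,10,5,0
EB_PI_03,PISTACIA,B,SB03,YELLOW,10,3,0
EB_PI_04,PISTACIA,B,SB04,DIGESTED,10,8,0
EB_PI_04,PISTACIA,B,SB04,RED,10,3,0
EB_PI_04,PISTACIA,B,SB04,YELLOW,10,2,0
EB_PI_05,PISTACIA,B,SB05,DIGESTED,10,3,0
EB_PI_05,PISTACIA,B,SB05,RED,10,5,2
EB_PI_05,PISTACIA,B,SB05,YELLOW,10,2,0
EB_PI_06,PISTACIA,B,SB06,DIGESTED,10,2,0
EB_PI_06,PISTACIA,B,SB06,RED,10,8,0
EB_PI_06,PISTACIA,B,SB06,YELLOW,10,2,0
EB_PI_07,PISTACIA,B,SB07,DIGESTED,10,4,0
EB_PI_07,PISTACIA,B,SB07,RED,10,6,0
EB_PI_07,PISTACIA,B,SB07,YELLOW,10,0,0
EB_PI_08,PISTACIA,B,SB08,DIGESTED,10,4,0
EB_PI_08,PISTACIA,B,SB08,RED,10,1,0
EB_PI_08,PISTACIA,B,SB08,YELLOW,10,4,0
EB_PI_09,PISTACIA,B,SB09,DIGESTED,10,7,2
EB_PI_09,PISTACIA,B,SB09,RED,10,5,1
EB_PI_09,PISTACIA,B,SB09,YELLOW,10,1,0
EB_PI_10,PISTACIA,B,SB10,DIGESTED,10,3,1
EB_PI_10,PISTACIA,B,SB10,RED,10,4,0
EB_PI_10,PISTACIA,B,SB10,YELLOW,10,3,0
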