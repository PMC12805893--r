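name	sequence	chemistry	backbone
F18MOE	TmCAmCTTTmCATAATGmCTGG	MOEx18	PS
F18OMe	UCACUUUCAUAAUGCUGG	OMEx18	PS
F20PMO	ATTCACTTTCATAATGCTGG	PMOx20	PMO_NEUTRAL
ScrMOE	TATmCmCATGTTmCAGmCATTG	MOEx18	PS
ScrOMe	UAUCCAUGUUCAGCAUUG	OMEx18	PS
ScrPMO	TAAGTTGAATTATGCTCCCT	PMOx20	PMO_NEUTRAL
F14MOE	TTTmCATAATGmCTGG	MOEx14	PS
M14MOE	AmCTTTmCATAATGmCT	MOEx14	PS
L14MOE	TmCAmCTTTmCATAATG	MOEx14	PS
F10MOE	ATAATGmCTGG	MOEx10	PS
M10MOE	TTTmCATAATG	MOEx10	PS
L10MOE	TmCAmCTTTmCAT	MOEx10	PS
OMe1-6	TmCAmCTTTmCATAATGmCTGG	MOEx12,OMEx6	PS
OMe4-9	TmCAmCTTTmCATAATGmCTGG	MOEx9,OMEx6,MOEx3	PS
OMe7-13	TmCAmCTTTmCATAATGmCTGG	MOEx5,OMEx7,MOEx6	PS
OMe10-15	TmCAmCTTTmCATAATGmCTGG	MOEx3,OMEx6,MOEx9	PS
OMe13-18	TmCAmCTTTmCATAATGmCTGG	OMEx6,MOEx12	PS
OMe1-9	TmCAmCTTTmCATAATGmCTGG	MOEx9,OMEx9	PS
OMe1-12	TmCAmCTTTmCATAATGmCTGG	MOEx6,OMEx12	PS
OMe1-12/16-18	TmCAmCTTTmCATAATGmCTGG	OMEx3,MOEx3,OMEx12	PS
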