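patient_id,hs_crp_mg_l,below_lod,vas_cm,pain_category,tooth_type
P01,0,1,2,1,molar
P02,0,1,3,1,premolar
P03,0,1,4.5,2,molar
P04,0,1,5,2,molar
P05,1,0,5.5,2,premolar
P06,3,0,6,2,premolar
P07,8,0,6.5,2,incisor
P08,3.45,0,7.5,3,molar
P09,3.6,0,8,3,molar
P10,4,0,8.5,3,molar
P11,5.5,0,9,3,molar
P12,9,0,9.5,3,molar
P13,18,0,10,3,premolar
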