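sample_id,cohort,diagnosis_label,age_years,location,sex,outcome,followup_days,initial_diagnosis
INI25,study,RT,0.2,Soft-part,M,NA,NA,RT
INI29,study,RT,?,Kidney,M,NA,NA,RT
INI44,study,RT,7.3,Kidney,M,NA,NA,RT
INI53,study,RT,0.7,Periph. nerve,M,NA,NA,RT
INI61,study,RT,8,"Thx, pararachis",M,NED,1825,RT
INI64,study,RT,21,Forearm,M,DOD,300,RT
INI105,study,RT,33,Retro-periton.,F,DOD,66,RT
INI116,study,RT,3.4,Foot,M,NED,1370,RT
INI120,study,RT,18,Paraspinal/ORL,F,DOD,774,RT
INI127,study,RT,40,Groin,M,NED,790,ES
INI135,study,RT,22,Fro. meninges,M,NED,60,RT
INI136,study,RT,14,Brachial plexus,M,NED,1005,RT
INI143,study,RT,10,Kidney,M,NED,610,RT
INI174,study,RT,27,"Soft-part, limb",M,DOD,172,MyoEC
INI176,study,RT,28,"Soft-part, leg",F,NA,NA,RT
INI185,study,RT,43,Vulva,F,NA,NA,MyoEC
INI20,study,SD-NRT,6.7,Adrenal Gland,M,DOD,120,RT
INI21,study,SD-NRT,1.6,Kidney,F,DOD,179,RT
INI37,study,ES,25,Lung,F,DOD,51,RT
INI38,study,SD-NRT,0.8,Bladder,M,DOD,90,RT
INI65,study,SD-NRT,54,Periph. nerve,F,DOD,93,eMPNST
INI86,study,SD-NRT,6,Thorax,M,NED,13yrs,RT
INI106,study,SD-NRT,1.2,Soft-parts,M,NED,988,RT
INI114,study,SD-NRT,26,Thorax,F,DOD,387,RT
INI115,study,SD-NRT,26,Cavum,F,NED,855,SD-NRT
INI117,study,UC,16,Paraspinal,M,DOD,122,RT
INI123,study,SD-NRT,38,Not found,F,DOD,260,ES
INI128,study,ES,13,Leg,M,NED,422,ES
INI129,study,SD-NRT,53,Groin,F,NA,NA,SD-NRT
INI130,study,ES,9,Buttock,F,NED,810,ES
INI131,study,SD-NRT,31,Pleura,M,DOD,155,RT
INI132,study,SD-NRT,39,Para. meninges,M,NED,239,AT/RT
INI133,study,ES,10,Elbow,M,NED,684,ES
INI134,study,ES,34,Abdomen,M,DOD,7,RT
INI152,study,SD-NRT,30,Periph. nerve,F,DOD,45,MPNST
INI175,study,ES,14,Neck,F,DOD,910,RT
INI182,study,SD-NRT,51,Kidney,M,NED,-,RT
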