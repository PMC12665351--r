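sow_id,posture_1,posture_2,posture_3,voc_1,voc_2,voc_3,voc_4,shave_time_s,touches,intervention_moment,hair_density,contemporary_group
sow0001,LDL,LDS,LDS,NONE,SGT,,SGT,43,0,none,2,week1
sow0002,LDS,STD,STD,SGT,SGT+LGT,LGT,SGT+LGT+BRK,78,2,between_sites,1,week1
sow0003,LDS,LDS,LDS,NONE,NONE,,NONE,35,0,none,2,week1
sow0004,SIT,STD,STD,LGT,LGT+BRK,BRK,BRK,102,3,before_first_site,3,week2
sow0005,LDL,LDL,LDS,NONE,SGT,,NONE,51,1,none,2,week2
sow0006,STD,SIT,LDS,SGT,NONE,SGT,NONE,64,1,between_sites,1,week2
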