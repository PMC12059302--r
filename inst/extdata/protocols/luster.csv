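# LUSTER constraint set used for 60 Gy / 8 fraction lung SBRT plans.
# See rtog0915.csv for the column conventions.
structure,category,metric,threshold,limit,unit,comparator,report_only
PTV,C3,PTV_VpctRx,90,99,%,>,FALSE
Lt Lung,C3,V_pct,20,10,%,<=,FALSE
Lt Lung,C1,Dmean,,6,Gy,<=,FALSE
Rt Lung,C3,V_pct,20,10,%,<=,FALSE
Rt Lung,C1,Dmean,,6,Gy,<=,FALSE
Trachea PRV,C2,V_cc,60,5,cc,<=,FALSE
Trachea PRV,C1,Dmax,,64,Gy,<=,FALSE
Esophagus PRV,C2,V_cc,22,5,cc,<=,FALSE
Esophagus PRV,C1,Dmax,,40,Gy,<=,FALSE
PB Tree,C2,V_cc,60,5,cc,<=,FALSE
PB Tree,C1,Dmax,,64,Gy,<=,FALSE
Heart,C2,V_cc,60,10,cc,<=,FALSE
Heart,C1,Dmax,,64,Gy,<=,FALSE
Aorta,C2,V_cc,60,10,cc,<=,FALSE
Aorta,C1,Dmax,,64,Gy,<=,FALSE
Spinal Cord PRV,C2,V_cc,22,1,cc,<=,FALSE
Spinal Cord PRV,C1,Dmax,,32,Gy,<=,FALSE
Chest Wall,C2,V_cc,30,70,cc,<=,FALSE
Skin,C2,V_cc,40,10,cc,<=,FALSE
Skin,C1,Dmax,,45,Gy,<,FALSE
Bone,C2,V_cc,30,,cc,,TRUE
Bone,C1,D2pct,,,Gy,,TRUE
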