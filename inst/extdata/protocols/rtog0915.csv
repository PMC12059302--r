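# RTOG 0915 constraint set used for 48 Gy / 4 fraction lung SBRT plans.
# metric: Dmean | Dmax (dose to the hottest 0.03 cc) | D2pct | V_cc | V_pct | PTV_VpctRx
# threshold: dose threshold in Gy for V_cc/V_pct; percent of prescription for PTV_VpctRx
# report-only rows (bone) carry no limit and are excluded from pass/fail denominators
structure,category,metric,threshold,limit,unit,comparator,report_only
PTV,C3,PTV_VpctRx,90,99,%,>,FALSE
Lt Lung,C3,V_pct,20,10,%,<=,FALSE
Lt Lung,C1,Dmean,,6,Gy,<=,FALSE
Rt Lung,C3,V_pct,20,10,%,<=,FALSE
Rt Lung,C1,Dmean,,6,Gy,<=,FALSE
Trachea PRV,C2,V_cc,15.6,4,cc,<=,FALSE
Trachea PRV,C1,Dmax,,34.8,Gy,<=,FALSE
Esophagus PRV,C2,V_cc,18.8,5,cc,<=,FALSE
Esophagus PRV,C1,Dmax,,30,Gy,<=,FALSE
PB Tree,C2,V_cc,15.6,4,cc,<=,FALSE
PB Tree,C1,Dmax,,34.8,Gy,<=,FALSE
Heart,C2,V_cc,28,15,cc,<=,FALSE
Heart,C1,Dmax,,34,Gy,<=,FALSE
Aorta,C2,V_cc,28,15,cc,<=,FALSE
Aorta,C1,Dmax,,34,Gy,<=,FALSE
Spinal Cord PRV,C2,V_cc,20.8,0.35,cc,<=,FALSE
Spinal Cord PRV,C2,V_cc,13.6,1.2,cc,<=,FALSE
Spinal Cord PRV,C1,Dmax,,26,Gy,<=,FALSE
Chest Wall,C2,V_cc,30,70,cc,<=,FALSE
Skin,C2,V_cc,33.2,10,cc,<=,FALSE
Skin,C1,Dmax,,36,Gy,<,FALSE
Bone,C2,V_cc,30,,cc,,TRUE
Bone,C1,D2pct,,,Gy,,TRUE
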