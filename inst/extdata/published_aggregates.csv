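quintile,inc_cost_per_person,inc_qaly_per_person,eligible_share,total_cost,total_qalys,hoc
Q1,61.29,0.0052,0.17,2869500,244,350
Q2,64.65,0.0062,0.19,3377577,323,291
Q3,63.59,0.0064,0.21,3717354,374,288
Q4,59.84,0.0054,0.22,3674595,331,212
Q5,58.91,0.0061,0.22,3585851,370,185
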