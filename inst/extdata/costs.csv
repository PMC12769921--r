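item,cost
invitation,2.13
reinvitation,2.13
screening_scan,40.43
surveillance_scan,85.37
surveillance_scan_turndown,85.37
consultation,352.41
elective_evar,15645.68
elective_open,14732.84
emergency_evar,22283.91
emergency_open,22608.57
reintervention_elective_evar,10253.39
reintervention_elective_open,13687.78
reintervention_emergency_evar,10253.39
reintervention_emergency_open,13687.78
surveillance_post_evar,298.84
surveillance_post_open,211.02
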