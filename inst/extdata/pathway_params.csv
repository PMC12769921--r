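item,Q1,Q2,Q3,Q4,Q5,best_case
p_reinvite,0.3609,0.3030,0.2505,0.2166,0.1865,
p_attend,0.6736,0.7403,0.7895,0.8157,0.8342,Q5
p_nonvisualised,0.0187,0.0150,0.0117,0.0104,0.0090,Q5
p_dropout,0.0481,0.0395,0.0381,0.0407,0.0415,Q3
wait_consult,0.0538,0.0605,0.0473,0.0413,0.0515,Q4
wait_surgery,0.3445,0.3461,0.2847,0.2980,0.3263,Q3
elective_open_intercept,5.53,6.22,5.92,7.09,6.67,Q4
elective_open_age,-0.11,-0.11,-0.11,-0.12,-0.12,Q4
elective_open_aorta,0.03,-0.02,0.02,0.02,0.02,Q4
emergency_open_intercept,2.06,3.50,3.99,2.35,0.73,Q5
emergency_open_age,-0.02,-0.04,-0.047,-0.025,-0.004,Q5
mort_elective_evar_intercept,-3.59,-3.59,-3.59,-3.59,-3.59,
mort_elective_evar_age,-0.03,-0.03,-0.03,-0.03,-0.03,
mort_elective_evar_aorta,0.01,0.01,0.01,0.01,0.01,
mort_elective_open_intercept,-4.11,-4.11,-4.11,-4.11,-4.11,
mort_elective_open_age,-0.07,-0.07,-0.07,-0.07,-0.07,
mort_elective_open_aorta,0.03,0.03,0.03,0.03,0.03,
mort_emergency_evar_intercept,-5.60,-5.60,-5.60,-5.60,-5.60,
mort_emergency_evar_age,0.02,0.02,0.02,0.02,0.02,
mort_emergency_open_intercept,-17.68,-17.68,-17.68,-17.68,-17.68,
mort_emergency_open_age,0.18,0.18,0.18,0.18,0.18,
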