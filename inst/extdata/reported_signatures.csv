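signature,site,network,state,comparison,p_value,cohens_d
1,left_motor,sensorimotor,mixed,post_controls_vs_patients,0.00003,0.85
2,left_motor,visual,active,patients_pre_vs_post,0.000036,0.64
3,vermis,frontoparietal,inactive,post_controls_vs_patients,0.000048,1.09
4,vermis,frontoparietal,active,post_controls_vs_patients,0.0000099,1.85
5,vermis,salience,inactive,post_controls_vs_patients,0.00014,1.38
6,vermis,salience,active,post_controls_vs_patients,0.0000015,1.53
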