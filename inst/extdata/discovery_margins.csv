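variable,cad_neg,cad_pos
patients,38,79
sex_male,13,47
hypertension,10,40
diabetes,2,6
hyperlipidaemia,15,47
current_smoking,5,8
smoking_history_gt10py,5,18
smurfless,12,11
family_history,11,22
antiplatelet,8,15
statin,7,31
beta_blocker,5,14
ace_arb,8,33
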