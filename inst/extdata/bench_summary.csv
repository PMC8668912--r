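group,cd_mg_l,qd_ml_h,percent_change_pct,note
loss_range,0,NA,-8.8,minimum loss with unenriched dialysate across the 3x3 flow grid
loss_range,0,NA,-35.6,maximum loss with unenriched dialysate across the 3x3 flow grid
gain_range,64,NA,18.7,minimum gain with 64 mg/L dialysate across the 3x3 flow grid
gain_range,64,NA,78.8,maximum gain with 64 mg/L dialysate across the 3x3 flow grid
qd_effect_loss,0,1000,-14.23,loss at 1000 ml/h dialysate flow (blood-flow stratification unreported)
qd_effect_loss,0,3000,-11.89,loss at 3000 ml/h dialysate flow (blood-flow stratification unreported)
qd_effect_gain,64,1000,19.91,gain at 1000 ml/h dialysate flow (blood-flow stratification unreported)
qd_effect_gain,64,3000,25.1,gain at 3000 ml/h dialysate flow (blood-flow stratification unreported)
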