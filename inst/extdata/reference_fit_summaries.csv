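method,subgroup,n,mean_true,sd_true,mean_pred,sd_pred,mae,mre
ann_with_gas,overall,257,623.3,325.7,651.4,329.0,38.1,0.058
harris_benedict,overall,257,623.3,325.7,824.3,260.2,244.2,0.610
schofield_w,overall,257,623.3,325.7,700.9,347.6,164.7,0.351
schofield_wh,overall,257,623.3,325.7,703.0,344.3,160.8,0.348
fao_who_unu,overall,257,623.3,325.7,701.4,353.1,168.7,0.358
oxford_w,overall,257,623.3,325.7,703.1,335.9,163.7,0.352
oxford_wh,overall,257,623.3,325.7,705.0,332.8,158.7,0.344
talbot_weight,overall,257,623.3,325.7,650.1,332.4,142.3,0.300
talbot_height,overall,257,623.3,325.7,675.6,325.5,147.6,0.320
mehta,ventilated,102,562.3,301.9,475.6,257.0,89.7,0.160
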