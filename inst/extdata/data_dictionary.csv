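variable,unit,description
id,-,record identifier
male,indicator,1 if male (male + female = 1)
female,indicator,1 if female
caucasian,indicator,ethnic origin indicator (the four sum to 1)
asian,indicator,ethnic origin indicator
south_american,indicator,ethnic origin indicator
african,indicator,ethnic origin indicator
mechanically_ventilated,indicator,1 if mechanically ventilated during measurement
age,years,age at measurement
weight,kg,body weight
height,cm,length or standing height
bmi,kg/m2,body mass index weight/(height/100)^2
z_bmi,z-score,BMI-for-age z-score (LMS reference)
z_hfa,z-score,height-for-age z-score
z_wfa,z-score,weight-for-age z-score; missing above 10 years
z_wfh,z-score,weight-for-length/height z-score; missing above 5 years
normal_weight,indicator,weight class indicator (exactly one of three)
overweight,indicator,weight class indicator
obese,indicator,weight class indicator
stunting,indicator,height-for-age z < -2
wasting_none,indicator,wasting grade indicator (the four sum to 1)
wasting_mild,indicator,age-appropriate z < -1
wasting_moderate,indicator,age-appropriate z < -2
wasting_severe,indicator,age-appropriate z < -3
vo2,L/min,oxygen consumption (indirect calorimetry)
vco2,L/min,carbon dioxide production
rq,-,respiratory quotient vco2/vo2
heart_rate,bpm,heart rate during measurement
sbp,mmHg,systolic blood pressure
dbp,mmHg,diastolic blood pressure
body_temperature,degC,body temperature
sat_o2,%,oxygen saturation
hemoglobin,g/dL,blood hemoglobin
blood_glucose,mg/dL,blood glucose
crp,mg/dL,C-reactive protein
measured_ree,kcal/day,resting energy expenditure measured by indirect calorimetry
true_ree,kcal/day,synthetic ground truth (generator only)
steady_start,minute,true steady-state window start (generator only)
steady_end,minute,true steady-state window end (generator only)
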