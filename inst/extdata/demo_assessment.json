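{"clinical_values":{"albuminuria_stage":"A1","bmi":27.4,"chol_hdl_ratio":4.5,"diastolic":95,"egfr":78,"fasting_glucose":6.8,"glucose_2h":9.5,"hba1c":58,"hdl":1.2,"ldl":3.1,"systolic":150,"total_cholesterol":5.4,"triglycerides":1.5,"waist_circumference":96,"waist_hip_ratio":0.95},"item_responses":{"alcohol":[1,5,1,2,2,0],"dsmq":[3,3,3,3,3,3,3,3],"eating":[2,250,0,1,1],"family":[1,2],"housing":[1,1],"income":[2],"loneliness":[2],"paid5":[1,1,0,1,0],"pain":[2],"perceived_health":[3],"pss":[1,2,1,3,2,1,3,2,0,1],"sedentary":[9,6],"smoking":[0,null,null],"squash_activity":[0,0,0,0,0,0,5,30,0,0],"who5":[3,2,3,2,2],"work":[1]},"patient_id":"demo-001","schema_id":"diag360/assessment","schema_version":"1.0","timepoint":"2026-02-03"}
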