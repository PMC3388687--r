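"name","type","units","required","description"
"patient_id","character","",TRUE,"Opaque patient identifier"
"age","numeric","years",TRUE,"Age at ICU admission (>= 18)"
"apache2","integer","points",TRUE,"Baseline APACHE II score (>= 0)"
"sofa","integer","points",TRUE,"Baseline SOFA score (>= 0)"
"days_hosp_to_icu","numeric","days",TRUE,"Days from hospital admission to ICU admission (>= 0, fractional)"
"bmi","numeric","kg/m2",FALSE,"Body mass index (> 0, may be missing)"
"n_comorbid","integer","count",TRUE,"Number of comorbidities (0-5)"
"il6","numeric","pg/mL",FALSE,"Serum interleukin-6 (> 0, may be missing)"
"crp","numeric","mg/L",FALSE,"C-reactive protein (> 0, may be missing)"
"pct","numeric","ng/mL",FALSE,"Procalcitonin (> 0, may be missing)"
"oral_intake_pct","numeric","%",FALSE,"Estimated % oral intake in the week prior (0-100, may be missing)"
"weight_loss_pct","numeric","%",FALSE,"% weight loss in the last three months (>= 0, may be missing)"
"mort28","integer","0/1",TRUE,"28-day mortality (1 = dead by day 28)"
"mv_start_within_48h","integer","0/1",FALSE,"Mechanical ventilation started within 48 h of ICU admission"
"mv_days","numeric","days",TRUE,"Days on mechanical ventilation (0-28)"
"icu_days","numeric","days",TRUE,"ICU length of stay (>= 0)"
"energy_prescribed","numeric","kcal/day",FALSE,"Daily energy prescription from the baseline assessment (> 0)"
"energy_received_daily","list","kcal",FALSE,"Semicolon-separated daily kcal received, one per ICU day up to 14"
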