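sex,method,population,inc_per100k,prev_per1000,duration_years,dw,yld,pct_diff_yld,pct_diff_daly
male,incidence,39313,19.4,,21.5,0.346,56.7,38,10
male,prevalence,39313,,2.6,,0.346,35.4,,
female,incidence,42443,17.2,,19.7,0.346,49.8,29,10
female,prevalence,42443,,2.4,,0.346,35.2,,
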