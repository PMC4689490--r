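state,dw,male,male_lo,male_hi,female,female_lo,female_hi,both,both_lo,both_hi
reference,0.346,44.6,38.4,50.5,40.1,33.9,46.4,84.8,76.5,93.8
treated_seizure_free,0.072,9.3,7.6,9.6,8.4,6.9,8.9,17.6,16.4,18.6
treated_recent_seizures,0.319,41.2,37.7,47.8,37.0,28.7,39.5,78.2,75.6,82.6
untreated,0.42,54.2,44.4,59.9,48.7,45.3,54.5,102.9,92.1,112.5
severe,0.657,84.8,74.0,98.6,76.2,64.6,83.8,161.0,142.9,170.5
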