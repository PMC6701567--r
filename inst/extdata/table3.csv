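sex,age_group,costs_avoided,qalys_gained,n_hit_short,n_lit_short,costs_short,qalys_short,n_hit_long,n_lit_long,costs_long,qalys_long
women,20-24,8142,0.61,0,1,-8142,-0.61,0,0,0,0
women,25-29,8425,0.65,1,0,8425,0.65,0,0,0,0
women,35-39,9267,0.71,2,2,0,0,1,1,0,0
women,40-44,8532,0.71,5,0,42658,3.55,4,0,34126,2.84
women,45-49,6772,0.66,3,3,0,0,1,2,-6772,-0.66
women,50-54,5228,0.61,4,3,5228,0.61,1,2,-5228,-0.61
women,55-59,4542,0.43,4,2,9085,0.86,4,1,13627,1.29
women,60-64,3336,0.32,4,0,13342,1.29,2,0,6671,0.64
women,65-69,2023,0.33,0,1,-2023,-0.33,0,0,0,0
men,20-24,10430,0.74,1,0,10430,0.74,1,0,10430,0.74
men,40-44,10526,1.00,1,0,10526,1.00,1,0,10526,1.00
men,45-49,11416,0.82,1,1,0,0,1,1,0,0
men,50-54,11360,0.78,0,1,-11360,-0.78,0,0,0,0
men,65-69,4084,0.46,1,0,4084,0.46,1,0,4084,0.46
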