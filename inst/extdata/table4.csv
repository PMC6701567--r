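quantity,cea_short,cea_long,cea_long_sensitivity,per_person_men,per_person_women
intervention_cost_hit,117011,117011,117011,801,801
intervention_cost_lit,27927,27927,27927,189,189
intervention_cost_diff,89085,89085,89085,612,612
societal_costs_avoided,82253,67466,32469,779,502
incremental_cost,6832,21619,56616,-167,110
incremental_qalys,7.44,5.71,4.82,0.0664,0.0462
icer,918,3786,11746,NA,2391
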