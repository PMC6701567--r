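gender,costs_avoided,qalys_gained
men,9740,0.83
women,7165,0.66
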