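season,vessels_observed,presence_fraction,mean_vessels_present,se_vessels_present
Summer,403,0.55,1.99,0.02
Autumn,422,0.52,1.87,0.02
Winter,125,0.44,1.21,0.02
Spring,253,0.49,1.90,0.02
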