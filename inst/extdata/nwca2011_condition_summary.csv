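key,value
sites_screened,1138
least_sites,277
intermediate_sites,530
most_sites,331
least_mean_tC_ha,407
most_mean_tC_ha,236
deep_layers_described,1287
deep_bd_modelled,899
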