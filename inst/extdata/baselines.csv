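attribute,value,sd,n
overall_acceptance,6.2,1.4,50
color_acceptance,6.3,1.5,50
flavor_acceptance,6,1.7,50
L_star,40.6,1.73,
moisture_pct,23.58,1.68,
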