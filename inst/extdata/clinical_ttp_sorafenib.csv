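# Median time to progression [months] with 90% CI reported for sorafenib
# (400 mg twice daily) in hepatocellular carcinoma, Asian populations:
# Park 2011, Qin 2013, Kudo 2011, Lyu 2019.
# Observed reference values for overlays and containment checks only.
study,n_patients,median_ttp_months,ci90_lo,ci90_hi
Park,169,3.6,3.1,3.8
Qin,331,3.6,3.1,3.7
Kudo,103,3.5,2.7,4.3
Lyu,132,4.3,3.7,4.9
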