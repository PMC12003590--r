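# Median time to progression [months] with 90% CI reported for single-agent
# gemcitabine (standard weekly schedule) in advanced pancreatic cancer:
# Hong 2013, Kindler 2011, Nakai 2012, Ozaka 2012.
# Observed reference values for overlays and containment checks only.
study,n_patients,median_ttp_months,ci90_lo,ci90_hi
Hong,56,3.9,3.2,6.7
Kindler,316,7.5,6.2,7.8
Nakai,53,4.7,2.2,6.6
Ozaka,59,5.6,3.3,7.1
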