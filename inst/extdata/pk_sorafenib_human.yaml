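# Illustrative human sorafenib PK: one-compartment disposition with a
# four-stage transit-compartment absorption chain for the oral delay.
# Magnitudes match published sorafenib population PK (apparent clearance
# of a few L/h, large apparent volume, tmax of several hours); synthetic
# defaults, not a transcription of any specific published estimate.
# The enterohepatic-recirculation component of published sorafenib models
# is deliberately not represented here; an externally supplied profile
# (read_concentration_csv) can carry such secondary peaks.
# Units: L and days.
n_compartments: 1
cl: 120       # L/day (= 5 L/h apparent)
vc: 210       # L (apparent)
absorption: transit
n_transit: 4
ktr: 24       # 1/day -> mean absorption delay of 4 h over the chain
f: 1
time_unit: day
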