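# Illustrative human gemcitabine PK: two-compartment disposition with
# linear elimination, i.v. input. Parameter magnitudes match published
# population analyses of gemcitabine (very high clearance, short terminal
# half-life); these are synthetic defaults, not a transcription of any
# specific published estimate. Replace with study-specific values as
# needed. Units: L and days.
n_compartments: 2
cl: 2700      # L/day (~112 L/h)
vc: 14        # L
q: 240        # L/day
vp: 20        # L
absorption: iv
f: 1
time_unit: day
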