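# Illustrative mouse PK for an i.p.-dosed chemotherapeutic: two-compartment
# disposition with a first-order absorption compartment. Synthetic defaults
# used by the panel generator; units L and days, 25 g mouse.
n_compartments: 2
cl: 1.5       # L/day
vc: 0.05      # L
q: 0.15       # L/day
vp: 0.05      # L
absorption: first_order
ka: 50        # 1/day (~20 min absorption half-life)
f: 1
time_unit: day
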