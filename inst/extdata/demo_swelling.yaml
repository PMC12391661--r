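# Demo equilibrium-swelling input for the Flory-Rehner mesh-size calculator
# (porehull mesh --config demo_swelling.yaml). Masses in grams; PEG/PBS
# constants left at their defaults.
m_wet_relaxed: 0.160
m_wet_swollen: 0.230
m_dry_relaxed: 0.010
M_n: 20000
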