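# Default force-field settings (flat TOML).  eps_stst is the single free
# energy-scale parameter of the contact potential; the mixed and
# spacer-spacer depths are derived as eps_stst/1.5 and eps_stst/3.
eps_stst = 1.0            # kJ/mol, sticker-sticker LJ well depth
debye_length = 1.0        # nm (about 100 mM ionic strength)
lj_cutoff = 2.0           # nm
coulomb_cutoff = 3.5      # nm
dielectric_prefactor = 1.7366932  # kJ mol^-1 nm e^-2 (ke / 80)
bond_r0 = 0.38            # nm
bond_k = 1000             # kJ mol^-1 nm^-2
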