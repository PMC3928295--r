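# example run configuration
rhf_basis: 6-31G(d)
mp2_basis: cc-pVDZ
dimer_cutoff: 1.5
polarization_enabled: true
fdd_enabled: true
gradient_tolerance: 1.0e-4
restraint_force_constant: 500
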