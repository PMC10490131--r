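# Variation ranges of the Rolie-Poly molecular parameters (SI units)
# used for surrogate training and as the inverse-solver search box.
eta_p:            # zero-shear polymer viscosity, Pa s
  min: 1
  max: 6000
  scale: log
tau_D:            # reptation / disengagement time, s
  min: 1
  max: 5000
  scale: log
tau_R:            # Rouse / stretch time, s
  min: 1
  max: 50
  scale: log
chi_max:          # maximum chain stretch ratio, dimensionless
  min: 15
  max: 20
  scale: linear
beta:             # convective constraint release coefficient, dimensionless
  min: 1
  max: 25
  scale: linear
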