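# Calibrated constants of the 2D Flory spreading-force model.
# Each value is a biologically reasonable choice, fixed once:
#   b          glucan segment length (~ one glucose unit), nm
#   sigma      areal density of growing chains (synthase-complex scale), 1/nm^2
#   nu         2D self-avoiding-walk Flory exponent
#   alpha      order-one prefactor of the semi-dilute 2D pressure law
#   plate_area mature cell-plate area, nm^2 (disc of 3 um radius)
#   tau        spreading-mat establishment time, s
b: 0.5
sigma: 5.0e-4
nu: 0.75
alpha: 1.0
plate_area: 2.8274334e+07
tau: 40.0
temperature: 298.15
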