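# Internal unit system: MOhm, uS, nF, nA, mV, ms, um, mM.
# Public physiological parameters use the NEURON conventions
# (uF/cm^2, S/cm^2, Ohm*cm, mV, ms, um, mM) and are converted at the
# boundary with the constants below.
#
#   conductance density: 1 S/cm^2   = 1e-2 uS/um^2
#   capacitance density: 1 uF/cm^2  = 1e-5 nF/um^2
#   axial resistivity:   1 Ohm*cm   = 1e-2 MOhm*um
#
# With these, uS * mV = nA, nF * mV / ms = nA, and mV / nA = MOhm, so the
# cable quantities r (MOhm/um), y_m (uS/um), z_c (MOhm) need no further
# conversion.

.G_FACT <- 1e-2   # S/cm^2  -> uS/um^2
.C_FACT <- 1e-5   # uF/cm^2 -> nF/um^2
.RA_FACT <- 1e-2  # Ohm*cm  -> MOhm*um
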