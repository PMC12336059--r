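# Synthetic default coefficients for the quadratic-relaxivity blood T2 /
# venous oxygenation calibration model
#   R2(Yv, Hct) = a(Hct) + b(Hct)*(1 - Yv) + c(Hct)*(1 - Yv)^2   [R2 in 1/s]
# with a = a1 + a2*Hct, b = b1 + b2*Hct, c = c1 + c2*Hct.
#
# These values are a SYNTHETIC stand-in chosen to give physiologically
# plausible venous T2 (~45-70 ms over Yv 0.45-0.65 at Hct 0.40-0.42); they
# are not published calibration constants.  Supply a file with validated
# coefficients for real-data use.  All package tests rely on round-trip
# consistency only.
a1: 3.0
a2: 2.5
b1: 5.0
b2: 25.0
c1: 10.0
c2: 50.0
yv_min: 0.05
yv_max: 0.98
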