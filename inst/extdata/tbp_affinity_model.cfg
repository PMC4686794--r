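# tatakit TBP affinity model configuration, v1
# Three-component windowed model of TBP / core-promoter binding:
#   -ln KD = intercept + w_pwm * pwm + w_groove * groove + w_slide * slide
# Coefficients are NOT stored here: they are calibrated at load time by
# ordinary least squares on the six shipped 26-bp probe / measured-affinity
# pairs (see tatakit::probeKinetics), a smoke-level calibration (n = 6).
version: 1
window_length: 26
delta_floor: 0.05
provenance: packaged default; TATAWAWR-style core frequencies; representative B-DNA minor-groove step widths (Angstrom)

# Position frequency matrix of the TATA-box core (columns = positions 1..8,
# consensus T A T A W A W R). Converted to ln-odds against the background.
pwm_frequencies:
A 0.04 0.91 0.07 0.64 0.74 0.92 0.45 0.32
C 0.09 0.03 0.02 0.02 0.02 0.02 0.06 0.12
G 0.04 0.01 0.02 0.04 0.02 0.02 0.10 0.44
T 0.83 0.05 0.89 0.30 0.22 0.04 0.39 0.12

background: 0.25 0.25 0.25 0.25

# Minor-groove width per dinucleotide step, Angstrom; strand-symmetric
# (value of a step equals that of its reverse complement). Narrow A-tract
# steps, intermediate mixed steps, wide G/C-rich steps.
groove_widths:
AA 3.0
AT 3.4
TA 4.2
AC 4.0
AG 4.3
CA 4.9
GA 4.3
CC 4.6
CG 5.2
GC 4.7
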