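# Segment mass as a fraction of total body mass, per single segment.
# Source: Dempster (1955) cadaver coefficients as tabulated by Winter,
# Biomechanics and Motor Control of Human Movement. Bilateral segments
# (thigh, shank, foot, upper_arm, forearm, hand) are listed once; double
# the fraction to account for both sides.
segment,fraction
head_neck,0.081
trunk,0.497
thigh,0.100
shank,0.0465
foot,0.0145
upper_arm,0.028
forearm,0.016
hand,0.006
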