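# Minimal example of the plain-text backbone-dependent rotamer library
# dialect read by read_bbdep_library().
#
# Two layouts are accepted per data line (whitespace-separated):
#   13 fields: aa phi psi count probability chi1-4 means chi1-4 sigmas
#   17 fields: aa phi psi count r1 r2 r3 r4 probability chi1-4 chi1-4sig
#              (the Dunbrack 2010 bbdep text layout)
# Angles in degrees; probabilities are renormalized per (aa, phi, psi) key.
SER  -60  -40  120  0.55   62   0   0   0   8.5  10  10  10
SER  -60  -40  120  0.30  -65   0   0   0   8.5  10  10  10
SER  -60  -40  120  0.15  180   0   0   0   8.5  10  10  10
LEU  -60  -40   80  0.60  -65 175   0   0   8.0   9  10  10
LEU  -60  -40   80  0.40  180  65   0   0   8.0   9  10  10
VAL -120  130   50  0.70  175   0   0   0   7.5  10  10  10
VAL -120  130   50  0.30  -60   0   0   0   7.5  10  10  10
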