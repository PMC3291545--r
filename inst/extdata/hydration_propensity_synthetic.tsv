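# SYNTHETIC stand-in hydration-propensity table.
# Per-atom-type hydration propensities of this kind are estimated from
# surveys of surface waters in high-resolution crystal structures; the
# published per-atom values are not redistributed here, so these defaults
# are plausible synthetic placeholders on the same [0, 1] scale.  Replace
# this file with measured values for production use.  Rows with residue
# "*" are element-class fallbacks (atom column holds the element symbol).
residue	atom	h
ALA	N	0.26
ALA	O	0.53
ASP	OD1	0.81
ASP	OD2	0.81
GLU	OE1	0.81
GLU	OE2	0.81
SER	OG	0.63
THR	OG1	0.63
TYR	OH	0.55
ASN	OD1	0.74
ASN	ND2	0.49
GLN	OE1	0.74
GLN	NE2	0.49
LYS	NZ	0.61
ARG	NE	0.44
ARG	NH1	0.64
ARG	NH2	0.64
HIS	ND1	0.56
HIS	NE2	0.56
TRP	NE1	0.31
CYS	SG	0.10
MET	SD	0.10
*	O	0.55
*	N	0.45
*	S	0.10
*	P	0.20
*	C	0.00
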