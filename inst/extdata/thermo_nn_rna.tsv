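# RNA Watson-Crick nearest-neighbor stacking parameters (Xia et al. 1998).
# step: 5'->3' dinucleotide of the strand under evaluation; the value is for
# the stack that step forms with its Watson-Crick complement, so reverse-
# complementary steps share one value (e.g. AA and UU).
# dG37 and dH in kcal/mol; dS in cal/(mol K). Stacks only: duplex-initiation
# and terminal corrections are deliberately excluded.
step	dG37	dH	dS
AA	-0.93	-6.82	-19.0
AC	-2.24	-11.40	-29.5
AG	-2.08	-10.48	-27.1
AU	-1.10	-9.38	-26.7
CA	-2.11	-10.44	-26.9
CC	-3.26	-13.39	-32.7
CG	-2.36	-10.64	-26.7
CU	-2.08	-10.48	-27.1
GA	-2.35	-12.44	-32.5
GC	-3.42	-14.88	-36.9
GG	-3.26	-13.39	-32.7
GU	-2.24	-11.40	-29.5
UA	-1.33	-7.69	-20.5
UC	-2.35	-12.44	-32.5
UG	-2.11	-10.44	-26.9
UU	-0.93	-6.82	-19.0
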