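# Published surface composition (at.%) of the nanofiber samples from XPS
# survey quantification; traces of Na/Cl/P excluded.
sample	C_at	O_at	N_at
PCL-ref	73.9	26.1	0.0
PCL-APO	75.8	22.0	2.2
PCL-ANG	78.0	22.0	0.0
PCL-COOH	72.3	27.5	0.3
PCL-COOH-APO	72.6	24.5	2.9
PCL-COOH-ANG	72.4	26.5	1.1
PCL-COOH-FN	71.3	23.1	5.6
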