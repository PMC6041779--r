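# Torsion-angle reference grid, class: general (v1)
# 36x36 bins of 10 degrees. Row 1: psi (170,180]; row 36: psi (-180,-170].
# Col 1: phi [-180,-170); col 36: phi [170,180). F favored, A allowed, O disallowed.
AFFFFFFFFFFFFAOOOOOOOOOOOOOOOOOOOOOO
AFFFFFFFFFFFFAOOOOOOOOOOOOOOOOOOOOOO
AFFFFFFFFFFFFAOOOOOOOOOOOOOOOOOOOOOO
AFFFFFFFFFFFFAOOOOOOOOOOOOOOOOOOOOOO
AFFFFFFFFFFFFAOOOOOOOOOOOOOOOOOOOOOO
AFFFFFFFFFFFFAOOOOOOOOOOOOOOOOOOOOOO
AFFFFFFFFFFFFAOOOOOOOOOOOOOOOOOOOOOO
AFFFFFFFFFFFFAOOOOOOOOOOOOOOOOOOOOOO
AAAAAAAAAAAAAAOOOOOOOOOOOOOOOOOOOOOO
AAAAAAAAAAAAAAOOOOOOOOAAAAOOOOOOOOOO
AAAAAAAAAAAAAAOOOOOOOOAAAAOOOOOOOOOO
AAAAAAAAAAAAAAOOOOOOOOAAAAOOOOOOOOOO
AAAAAAAAAAAAAAOOOOOOOOAAAAOOOOOOOOOO
AAAAAAAAAAAAAAOOOOOOOAAAAAAOOOOOOOOO
AAAAAAAAAAAAAAOOOOOOOOAAAAOOOOOOOOOO
AAAAAAAAAAAAAAOOOOOOOOAAAAOOOOOOOOOO
AAAAAAAAAAAAAAOOOOOOOOAAAAOOOOOOOOOO
AAAAAAAAAAAAAAOOOOOOOOAAAAOOOOOOOOOO
AAAAAAAAAAFFFAOOOOOOOOOOOOOOOOOOOOOO
AAAAFFFFFFFFFFFOOOOOOOOOOOOOOOOOOOOO
AAAAFFFFFFFFFFFFOOOOOOOOOOOOOOOOOOOO
AAAAFFFFFFFFFFFFOOOOOOOOOOOOOOOOOOOO
AAAAFFFFFFFFFFFFOOOOOOOOOOOOOOOOOOOO
AAAAFFFFFFFFFFFFOOOOOOOOOOOOOOOOOOOO
AAAAFFFFFFFFFFFOOOOOOOOOOOOOOOOOOOOO
AAAAAAAAAFFFFFOOOOOOOOOOOOOOOOOOOOOO
AAAAAAAAAAAAAAOOOOOOOOOOOOOOOOOOOOOO
AAAAAAAAAAAAAAOOOOOOOOOOOOOOOOOOOOOO
AAAAAAAAAAAAAAOOOOOOOOOOOOOOOOOOOOOO
AAAAAAAAAAAAAAOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
AAAAAAAAAAAAAAOOOOOOOOOOOOOOOOOOOOOO
AAAAAAAAAAAAAAOOOOOOOOOOOOOOOOOOOOOO
AFFFFFFFFFFFFAOOOOOOOOOOOOOOOOOOOOOO
AFFFFFFFFFFFFAOOOOOOOOOOOOOOOOOOOOOO
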