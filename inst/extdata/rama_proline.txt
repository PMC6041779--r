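# Torsion-angle reference grid, class: proline (v1)
# 36x36 bins of 10 degrees. Row 1: psi (170,180]; row 36: psi (-180,-170].
# Col 1: phi [-180,-170); col 36: phi [170,180). F favored, A allowed, O disallowed.
OOOOOOOAAFFFFFAOOOOOOOOOOOOOOOOOOOOO
OOOOOOOAAFFFFFAOOOOOOOOOOOOOOOOOOOOO
OOOOOOOAAFFFFFAOOOOOOOOOOOOOOOOOOOOO
OOOOOOOAAFFFFFAOOOOOOOOOOOOOOOOOOOOO
OOOOOOOAAFFFFFAOOOOOOOOOOOOOOOOOOOOO
OOOOOOOAAFFFFFAOOOOOOOOOOOOOOOOOOOOO
OOOOOOOAAFFFFFAOOOOOOOOOOOOOOOOOOOOO
OOOOOOOAAAAAAAAOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOAAAAAAAAOOOOOOOOOOOOOOOOOOOOO
OOOOOOOAAAAFAAAOOOOOOOOOOOOOOOOOOOOO
OOOOOOOAAFFFFFAOOOOOOOOOOOOOOOOOOOOO
OOOOOOOAAFFFFFAOOOOOOOOOOOOOOOOOOOOO
OOOOOOOAFFFFFFFOOOOOOOOOOOOOOOOOOOOO
OOOOOOOAAFFFFFAOOOOOOOOOOOOOOOOOOOOO
OOOOOOOAAFFFFFAOOOOOOOOOOOOOOOOOOOOO
OOOOOOOAAAAFAAAOOOOOOOOOOOOOOOOOOOOO
OOOOOOOAAAAAAAAOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOOO
OOOOOOOAAAAAAAAOOOOOOOOOOOOOOOOOOOOO
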