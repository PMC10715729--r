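# Candidate structural equation models for the tissue analysis.
# Reconstruction of the described model families: direct vs indirect
# brumation effects (via digestive tract and/or body fat) on brain,
# testes and hindlimb muscles, with both brain->testes directions.
# Synthetic candidate set; not the original 28 models.

model m01
hindlimb <- brumation
brain <- brumation
testes <- brumation
fat <- brumation
testes <- fat

model m02
hindlimb <- brumation
brain <- brumation
fat <- brumation
testes <- fat

model m03
hindlimb <- brumation
brain <- brumation
testes <- brumation
fat <- brumation

model m04
hindlimb <- brumation
brain <- brumation
testes <- brumation
digestive <- brumation
fat <- digestive
testes <- fat

model m05
hindlimb <- brumation
brain <- brumation
digestive <- brumation
fat <- digestive
testes <- fat

model m06
hindlimb <- brumation
brain <- brumation
testes <- brumation
digestive <- brumation
fat <- digestive

model m07
hindlimb <- brumation
brain <- brumation
testes <- brumation
digestive <- brumation
fat <- brumation + digestive
testes <- fat

model m08
hindlimb <- brumation
brain <- brumation
digestive <- brumation
fat <- brumation + digestive
testes <- fat

model m09
hindlimb <- brumation
brain <- brumation
testes <- brumation
digestive <- brumation
fat <- brumation + digestive

model m10
hindlimb <- brumation
brain <- brumation
testes <- brumation
fat <- brumation
testes <- fat
testes <- brain

model m11
hindlimb <- brumation
brain <- brumation
fat <- brumation
testes <- fat
testes <- brain

model m12
hindlimb <- brumation
brain <- brumation
testes <- brumation
fat <- brumation
testes <- brain

model m13
hindlimb <- brumation
brain <- brumation
fat <- brumation
testes <- brain

model m14
hindlimb <- brumation
brain <- brumation
testes <- brumation
digestive <- brumation
fat <- digestive
testes <- fat
testes <- brain

model m15
hindlimb <- brumation
brain <- brumation
digestive <- brumation
fat <- digestive
testes <- fat
testes <- brain

model m16
hindlimb <- brumation
brain <- brumation
testes <- brumation
digestive <- brumation
fat <- digestive
testes <- brain

model m17
hindlimb <- brumation
brain <- brumation
digestive <- brumation
fat <- digestive
testes <- brain

model m18
hindlimb <- brumation
brain <- brumation
testes <- brumation
digestive <- brumation
fat <- brumation + digestive
testes <- fat
testes <- brain

model m19
hindlimb <- brumation
brain <- brumation
digestive <- brumation
fat <- brumation + digestive
testes <- fat
testes <- brain

model m20
hindlimb <- brumation
brain <- brumation
testes <- brumation
digestive <- brumation
fat <- brumation + digestive
testes <- brain

model m21
hindlimb <- brumation
brain <- brumation
digestive <- brumation
fat <- brumation + digestive
testes <- brain

model m22
hindlimb <- brumation
brain <- brumation
testes <- brumation
fat <- brumation
testes <- fat
brain <- testes

model m23
hindlimb <- brumation
brain <- brumation
fat <- brumation
testes <- fat
brain <- testes

model m24
hindlimb <- brumation
testes <- brumation
fat <- brumation
testes <- fat
brain <- testes

model m25
hindlimb <- brumation
fat <- brumation
testes <- fat
brain <- testes

model m26
hindlimb <- brumation
brain <- brumation
testes <- brumation
fat <- brumation
brain <- testes

model m27
hindlimb <- brumation
testes <- brumation
fat <- brumation
brain <- testes

model m28
hindlimb <- brumation
brain <- brumation
testes <- brumation
digestive <- brumation
fat <- digestive
testes <- fat
brain <- testes

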