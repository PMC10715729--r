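# Candidate structural equation models for the climate analysis:
# does latitude (seasonality proxy) drive breeding aggregations directly
# or through brumation duration and/or breeding-season length?
# Synthetic candidate set; editable without code changes.

model c1
brumation <- latitude
season <- brumation
aggregation <- season

model c2
brumation <- latitude
season <- brumation
aggregation <- season + brumation

model c3
brumation <- latitude
season <- latitude
aggregation <- season

model c4
brumation <- latitude
season <- brumation
aggregation <- brumation

model c5
brumation <- latitude
season <- brumation
aggregation <- latitude

model c6
brumation <- latitude
season <- latitude
aggregation <- brumation

model c7
brumation <- latitude
season <- brumation + latitude
aggregation <- season

model c8
brumation <- latitude
season <- latitude
aggregation <- latitude
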