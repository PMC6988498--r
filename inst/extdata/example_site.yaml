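# Example site configuration: a temperate cropland with a C4 (maize) crop
# planted in 1993 on a C3 (wheat) soil. Omitted keys take package defaults.
params:
  clay: 0.22
forcing:
  flux_above: 200
  flux_below: 200
  scenario:
    reference_delta: -27.9
    reference_year: 2005
    switch_year: 1993
run:
  start_year: 1901
  end_year: 2011
  output_every: 10
seed: 1
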