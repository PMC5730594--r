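# example run configuration for fdextinct::read_run_config()
seed: 1
n_random: 999
axis: s_minus_1
scenarios: [random, best, worst, abundance, trait, iucn]
generator:
  pool_size: 120
  coupling: 0.8
  n_sites:
    lake: 30
    river: 60
    estuary: 10
  richness_ranges:
    lake: [3, 19]
    river: [3, 31]
    estuary: [4, 57]
  iucn_proportions:
    LC: 0.72
    NT: 0.10
    VU: 0.09
    EN: 0.06
    CR: 0.03
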