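# External data

The package ships no species trait data: the original five-trait table for
the 271 monitored European fish species is distributed as journal
supplementary material, not through a public accession, so it cannot be
bundled here.

To run the cophenetic-fidelity check against it, save the table as

    fish_traits_271.csv

in this directory (before installation) with a header row and columns

    species, size, vertical_position, trophic_group, spawning_habitat,
    swimming_mode

using the category labels of `fish_trait_schema()`. The dendrogram built by
`build_upgma_dendrogram(gower_dissimilarity(...))` on that table has a
reported cophenetic correlation of 0.74 with the Gower matrix.

`example_config.yaml` is a small run configuration for
`read_run_config()` / `run_study()`.
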