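# dragonera_synthetic

A **synthetic** field dataset bundled for examples and tests. It reproduces
the published experimental design (two zones; 60 predation trays of 10 seeds
over three microhabitats, of which 7 are censored in the published pattern;
60 sowing stations with 10 seeds of each of three treatments) and the
published microhabitat percentage covers (open 45.1, Pistacia 27.0, Ephedra
17.5, remainder 10.4), but every outcome count was simulated with
`generate_field_dataset(paper_like_truth(), paper_design(), seed = 20170821,
censoring = "observed")`. It is a stand-in with known generating parameters,
not the study's raw data (which were never deposited).
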