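No fixture data ship with the package: every test input is generated
programmatically at test time by the synthetic-data module.

One optional file is recognised here:

  table_s1_pst.tsv  -- the published per-individual pod-shell-thickness
                       table of the 410 F2 plants (journal supplementary
                       material; not redistributable with this package).
                       Expected columns: an id column and a PST column
                       in mm (any column name containing "pst").

When present, the phenotype-statistics acceptance criterion in
tests/testthat/test-acceptance.R evaluates descriptive_stats() on it;
when absent, that one criterion reports an honest failure.
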