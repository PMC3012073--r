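Deposited survey tables (not redistributable; user-supplied)
============================================================

The strain-level validation in tests/testthat/test-acceptance.R recomputes
the published survey statistics from the deposited per-strain tables. Those
tables are distributed by their archives, not with this package. To run the
check, convert them to CSV and place here:

strain_averages.csv
  one row per strain; columns:
    strain, TST, OF_center_pct, OF_distance_cm, cort
  (strain averages: percent immobility, percent center time, distance in
  cm, baseline corticosterone in ug/dl)

animal_records.csv
  per-animal long form accepted by readPhenotypes():
    strain, animal_id, trait, value, excluded, reason

Without these files the corresponding test fails with a pointer to this
README; all other tests are self-contained.
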