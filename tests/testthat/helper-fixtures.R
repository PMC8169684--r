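# Shared fixtures, built once per test run. Problem sizes are kept small
# (tens of compounds, 5-fold CV with 1-2 repeats) so the whole suite runs in
# minutes; the generator seeds are fixed study conditions, not tuning knobs.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

scaffold_set <- function() fixture("scaffold_set", function() {
  generate_scaffold_classes(synthetic_spec(n_classes = 3, n_per_class = 25,
                                           seed = 7))
})

moa_bundle <- function() fixture("moa_bundle", function() {
  train_moa_model(scaffold_set(), min_count = 2, folds = 5, repeats = 1,
                  seed = 3)
})

selectivity_set <- function() fixture("selectivity_set", function() {
  generate_selectivity_set(synthetic_spec(n_per_class = 40, seed = 5))
})

selectivity_bundle <- function() fixture("selectivity_bundle", function() {
  train_selectivity_model(selectivity_set(), folds = 5, repeats = 1, seed = 4)
})

# Small hand-written compound table on disk
write_toy_csv <- function(path, bad_row = TRUE) {
  rows <- c("id,smiles,moa",
            "c1,CCO,A",
            "c2,CC(=O)[O-].[Na+],B",
            if (bad_row) "c3,C1CC,A",
            "c4,c1ccccc1,Z")
  writeLines(rows, path)
  path
}
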