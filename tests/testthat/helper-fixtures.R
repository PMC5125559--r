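# Shared fixtures, built once per test run.

.fixture_memo <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_memo[[key]])) .fixture_memo[[key]] <- builder()
  .fixture_memo[[key]]
}

# the published top-ten centrality table used as a worked prioritization input
table2_records <- function() {
  tibble::tribble(
    ~protein_id, ~sc, ~bc,
    "SACOL2213", 1.85e23, 0.0329,
    "SACOL0591", 2.76e23, 0.0198,
    "SACOL0588", 1.17e23, 0.0178,
    "SACOL2675", 1.01e23, 0.0128,
    "SACOL1292", 2.65e23, 0.0112,
    "SACOL0593", 2.82e23, 0.0093,
    "SACOL2234", 3.29e23, 0.0049,
    "SACOL2233", 3.11e23, 0.0047,
    "SACOL2207", 2.94e23, 0.0046,
    "SACOL0545", 1.06e23, 0.0045
  )
}

# a small labeled dataset with real features, shared across model tests
tiny_signal_dataset <- function() {
  memo("tiny_signal", function() {
    synthetic_dti_dataset(60, 60, effect_size = 8, seed = 301)
  })
}

tiny_null_dataset <- function() {
  memo("tiny_null", function() {
    synthetic_dti_dataset(60, 60, effect_size = 0, seed = 302)
  })
}
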