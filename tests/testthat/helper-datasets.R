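# Shared synthetic datasets, built once per test run and cached. The small
# dataset keeps module tests fast; the full-size dataset (study-condition
# defaults: 4 clades x 50 copies, 2% divergence, 8 diagnostic sites) backs
# the recovery and end-to-end checks.

.vmte_fixtures <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 424) {
  sim_config(seed = seed, instances_per_clade = 10, n_bg_subfamilies = 6,
             bg_copies = 6, n_novel = 5, n_background_peaks = 15)
}

get_small_dataset <- function() {
  if (is.null(.vmte_fixtures$small))
    .vmte_fixtures$small <- simulate_dataset(small_sim_config())
  .vmte_fixtures$small
}

get_small_dir <- function() {
  if (is.null(.vmte_fixtures$small_dir)) {
    dir <- file.path(tempdir(), "vmte-small")
    write_synthetic_dataset(get_small_dataset(), dir)
    .vmte_fixtures$small_dir <- dir
  }
  .vmte_fixtures$small_dir
}

get_full_dataset <- function() {
  if (is.null(.vmte_fixtures$full))
    .vmte_fixtures$full <- simulate_dataset(sim_config(seed = 515))
  .vmte_fixtures$full
}

get_full_dir <- function() {
  if (is.null(.vmte_fixtures$full_dir)) {
    dir <- file.path(tempdir(), "vmte-full")
    write_synthetic_dataset(get_full_dataset(), dir)
    .vmte_fixtures$full_dir <- dir
  }
  .vmte_fixtures$full_dir
}
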