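# The propensity-sweep experiment shared by the introgression, rescue and
# fragment-effect acceptance tests: 150 x 150 synthetic landscape with the
# reference fragment areas, propensities 0-100%, 10 replicates each. The
# population-level comparisons read the year-100 census; the h = 1%
# condition runs on to year 300 — the horizon of the reference fragment
# table — where its per-fragment heterozygosity is recorded. Computed once
# per test run and cached.
.crit_cache <- new.env(parent = emptyenv())

propensity_experiment <- function() {
  if (!is.null(.crit_cache$tbl)) {
    return(list(tbl = .crit_cache$tbl, fragments = .crit_cache$fragments))
  }
  hs <- c(0, 0.01, 0.05, 0.1, 0.5, 1)
  configs <- lapply(hs, function(h) {
    sim_config(h = h, years = if (h == 0.01) 300 else 100,
               replicates = 10, seed = 42,
               landscape_args = list(seed = 42),
               keep_final = FALSE, record_fragments = (h == 0.01))
  })
  tbl <- run_experiment(configs)
  .crit_cache$tbl <- dplyr::filter(tbl, .data$year <= 100)
  .crit_cache$fragments <- attr(tbl, "results")[[2]]$fragments
  list(tbl = .crit_cache$tbl, fragments = .crit_cache$fragments)
}
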