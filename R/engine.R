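#' Simulation configuration
#'
#' Full parameterization of one experiment condition. Replicate `r` runs
#' under seed `seed + r`, while the synthetic landscape (when no landscape is
#' supplied) is generated once under `seed` and shared by all replicates.
#'
#' @param landscape A `zos_landscape`, an AGC matrix, a path to a text grid,
#'   or `NULL` to generate a synthetic landscape from `landscape_args`.
#' @param scenario Scenario name (resolved against the landscape's derived
#'   scenarios) or a [scenario_spec()] object.
#' @param species Named list of [species_params()].
#' @param h Hybridization propensity in `[0, 1]`.
#' @param years Simulated years per replicate.
#' @param replicates Number of replicates.
#' @param genes_per_chromosome Genome layout (1, 2 or 4); values above 1
#'   model genetic linkage.
#' @param mutation `list(enabled, rate, sd)`; disabled by default (the model
#'   introduces variation through hybridization, not mutation).
#' @param seed Base seed.
#' @param focal Species whose population the per-year records track.
#' @param landscape_args Arguments passed to [generate_landscape()].
#' @param record_fragments Record per-fragment heterozygosity in the final
#'   year of each replicate.
#' @param keep_final Keep each replicate's final population table in the
#'   result (memory-heavy for large runs).
#' @param verbose Print per-replicate progress.
#' @return A `zos_config` object.
#' @export
sim_config <- function(landscape = NULL, scenario = "control",
                       species = default_species(), h = 0,
                       years = 300, replicates = 50,
                       genes_per_chromosome = 1,
                       mutation = list(enabled = FALSE, rate = 1e-3, sd = NULL),
                       seed = 1, focal = "silvanus",
                       landscape_args = list(),
                       record_fragments = FALSE, keep_final = TRUE,
                       verbose = FALSE) {
  stopifnot(h >= 0, h <= 1, years >= 0, replicates >= 1)
  validate_gpc(genes_per_chromosome)
  if (isTRUE(mutation$enabled) && is.null(mutation$sd)) {
    mutation$sd <- default_mutation_sd(species)
  }
  structure(list(landscape = landscape, scenario = scenario, species = species,
                 h = h, years = years, replicates = replicates,
                 genes_per_chromosome = genes_per_chromosome,
                 mutation = mutation, seed = seed, focal = focal,
                 landscape_args = landscape_args,
                 record_fragments = record_fragments,
                 keep_final = keep_final, verbose = verbose),
            class = "zos_config")
}

resolve_landscape <- function(config) {
  ls <- config$landscape
  if (is.null(ls)) {
    args <- config$landscape_args
    if (is.null(args$seed)) args$seed <- config$seed
    ls <- do.call(generate_landscape, args)
  } else if (is.character(ls)) {
    ls <- read_agc_grid(ls)
  } else if (is.matrix(ls)) {
    ls <- landscape(ls)
  }
  apply_scenario(ls, if (is.character(config$scenario)) {
    if (identical(config$scenario, "control") &&
        is.null(attr(ls, "scenarios"))) {
      scenario_spec("control")
    } else config$scenario
  } else config$scenario)
}

#' Initialize a simulation state
#'
#' @param ls A `zos_landscape` (scenario already applied).
#' @param config A `zos_config`.
#' @return State list with elements `population`, `landscape`, `year`,
#'   `next_id`.
#' @export
simulation_state <- function(ls, config) {
  pop <- initialize_population(ls, config$species, config$h,
                               config$genes_per_chromosome)
  list(population = pop, landscape = ls, year = 0L,
       next_id = if (nrow(pop)) max(pop$id) + 1L else 1L)
}

#' Advance a simulation state by one year
#'
#' Applies, in order, the three annual life-history processes: survival
#' (with widowing bookkeeping), reproduction of all intact pairs, and
#' juvenile natal dispersal with settlement and pairing. Birds that die take
#' no further part in the year; juveniles disperse in their natal year.
#'
#' @param state State list from [simulation_state()].
#' @param config A `zos_config`.
#' @return The advanced state.
#' @export
run_year <- function(state, config) {
  sp <- config$species
  surv <- vapply(sp, function(s) s$survival, numeric(1))
  names(surv) <- vapply(sp, function(s) s$tag, character(1))
  pop <- annual_survival(state$population, surv)
  juv <- reproduce_pairs(pop, sp,
                         mutation = if (isTRUE(config$mutation$enabled))
                           config$mutation else NULL,
                         next_id = state$next_id)
  next_id <- if (nrow(juv)) max(juv$id) + 1L else state$next_id
  disp <- disperse_juveniles(juv, pop, state$landscape, config$h)
  pop <- dplyr::bind_rows(disp$population, disp$settled)
  pop$age <- pop$age + 1L
  state$population <- pop
  state$year <- state$year + 1L
  state$next_id <- next_id
  state
}

#' Run a replicated simulation
#'
#' Builds the landscape, applies the scenario, and runs all replicates of
#' the annual cycle, recording the focal species' population size, admixture
#' heterozygosity and mean habitat traits every year (year 0 is the initial
#' state). Identical configurations (including the seed) give identical
#' results.
#'
#' @param config A `zos_config` from [sim_config()].
#' @return A `zos_result`: list with `years` (per-replicate, per-year
#'   records), `final` (list of final population tables if `keep_final`),
#'   `fragments` (final-year fragment heterozygosity if `record_fragments`),
#'   `landscape`, and `config`.
#' @export
run_simulation <- function(config) {
  ls <- resolve_landscape(config)
  frag <- NULL
  if (isTRUE(config$record_fragments)) {
    frag <- attr(ls, "fragments") %||% identify_fragments(ls)
  }
  years_l <- vector("list", config$replicates)
  frag_l <- vector("list", config$replicates)
  finals <- if (isTRUE(config$keep_final)) vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    withr::local_seed(config$seed + r)
    state <- simulation_state(ls, config)
    recs <- vector("list", config$years + 1L)
    recs[[1]] <- population_summary(state$population, config$focal)
    for (y in seq_len(config$years)) {
      state <- run_year(state, config)
      recs[[y + 1L]] <- population_summary(state$population, config$focal)
    }
    years_l[[r]] <- dplyr::bind_rows(recs) |>
      dplyr::mutate(replicate = r, year = 0:config$years, .before = 1)
    if (!is.null(frag)) {
      frag_l[[r]] <- fragment_heterozygosity(state$population, frag, ls,
                                             config$focal) |>
        dplyr::mutate(replicate = r, .before = 1)
    }
    if (isTRUE(config$keep_final)) finals[[r]] <- state$population
    if (isTRUE(config$verbose)) {
      message("replicate ", r, "/", config$replicates, ": N = ",
              years_l[[r]]$n_adults[config$years + 1L])
    }
  }
  structure(list(years = dplyr::bind_rows(years_l),
                 final = finals,
                 fragments = if (!is.null(frag)) dplyr::bind_rows(frag_l),
                 landscape = ls, config = config),
            class = "zos_result")
}

#' @export
print.zos_result <- function(x, ...) {
  cat("<zos_result> scenario=",
      if (is.character(x$config$scenario)) x$config$scenario else x$config$scenario$name,
      ", h=", x$config$h, ", ", x$config$replicates, " replicate(s) x ",
      x$config$years, " year(s)\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Tidy per-year records of a simulation result
#'
#' @param x A `zos_result`.
#' @param ... Unused.
#' @return Tibble with one row per (replicate, year).
#' @export
tidy.zos_result <- function(x, ...) {
  scen <- if (is.character(x$config$scenario)) x$config$scenario
          else x$config$scenario$name
  dplyr::mutate(x$years, scenario = scen, h = x$config$h, .before = 1)
}

#' One-row final-year summary of a simulation result
#'
#' Means over replicates of the focal species' final population size,
#' heterozygosity and habitat trait means.
#'
#' @param x A `zos_result`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.zos_result <- function(x, ...) {
  last <- dplyr::filter(x$years, .data$year == max(.data$year))
  tibble::tibble(
    years = x$config$years, replicates = x$config$replicates,
    h = x$config$h,
    scenario = if (is.character(x$config$scenario)) x$config$scenario
               else x$config$scenario$name,
    mean_final_n = mean(last$n_adults),
    mean_final_heterozygosity = mean(last$heterozygosity),
    mean_final_agc_optimum = mean(last$mean_agc_optimum),
    mean_final_agc_tolerance = mean(last$mean_agc_tolerance)
  )
}

#' Run a sweep of simulation configurations
#'
#' Runs each configuration in turn and concatenates the tidied per-year
#' records; results are independent of the order of the configurations.
#'
#' @param configs List of `zos_config` objects.
#' @return Tibble of per-year records keyed by `scenario`, `h`, `replicate`
#'   and `year`, with the individual `zos_result` objects in attribute
#'   `results`.
#' @export
run_experiment <- function(configs) {
  results <- purrr::map(configs, run_simulation)
  combined <- purrr::list_rbind(purrr::map(results, tidy))
  attr(combined, "results") <- results
  combined
}

#' Configurations for a hybridization-propensity sweep
#'
#' One configuration per propensity value, sharing all other settings. The
#' default propensities are 0, 1, 5, 10, 50 and 100%.
#'
#' @param h_values Propensity values.
#' @param ... Passed to [sim_config()].
#' @return List of `zos_config`.
#' @export
propensity_sweep <- function(h_values = c(0, 0.01, 0.05, 0.1, 0.5, 1), ...) {
  purrr::map(h_values, function(h) sim_config(h = h, ...))
}

#' Configurations for a habitat-scenario sweep
#'
#' One configuration per scenario over a shared landscape, holding the
#' hybridization propensity constant (default 1%).
#'
#' @param scenarios Scenario names.
#' @param h Hybridization propensity shared by all scenarios.
#' @param ... Passed to [sim_config()].
#' @return List of `zos_config`.
#' @export
habitat_sweep <- function(scenarios = c("control", "edge_depletion",
                                        "fragment_clearing",
                                        "corridor_planting",
                                        "plantation_conversion"),
                          h = 0.01, ...) {
  purrr::map(scenarios, function(s) sim_config(scenario = s, h = h, ...))
}
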