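#' Per-year population summary of one species
#'
#' Counts the settled adults carrying the species label, their gene pool's
#' admixture heterozygosity (percentage of extraspecific chromosomes) and
#' the arithmetic means of the expressed habitat traits. An empty population
#' yields zero adults and missing heterozygosity and means.
#'
#' @param population Population tibble.
#' @param species Species tag.
#' @return One-row tibble: `n_adults`, `heterozygosity`,
#'   `mean_agc_optimum`, `mean_agc_tolerance`.
#' @export
population_summary <- function(population, species = "silvanus") {
  sel <- population$species == species
  n <- sum(sel)
  if (n == 0) {
    return(tibble::tibble(n_adults = 0L, heterozygosity = NA_real_,
                          mean_agc_optimum = NA_real_,
                          mean_agc_tolerance = NA_real_))
  }
  gn <- population_genomes(population[sel, ])
  tibble::tibble(
    n_adults = n,
    heterozygosity = extraspecific_fraction(gn, species),
    mean_agc_optimum = mean(population$agc_optimum[sel]),
    mean_agc_tolerance = mean(population$agc_tolerance[sel])
  )
}

# per-bird extraspecific chromosome count
extra_chromosomes <- function(population, species) {
  sp <- match(species, zos_species_tags)
  rowSums(population$origin_a != sp) + rowSums(population$origin_b != sp)
}

#' Per-patch admixture heterozygosity map
#'
#' The extraspecific-chromosome percentage restricted to each patch's
#' residents of the given species; patches without such residents are
#' omitted. The global heterozygosity is exactly the chromosome-weighted
#' (here: resident-count-weighted) mean of the patch values.
#'
#' @param population Population tibble.
#' @param ls A `zos_landscape`.
#' @param species Species tag.
#' @return Tibble with columns `row`, `col`, `n`, `heterozygosity`.
#' @export
patch_heterozygosity <- function(population, ls, species = "silvanus") {
  pop <- population[population$species == species, ]
  if (nrow(pop) == 0) {
    return(tibble::tibble(row = integer(), col = integer(), n = integer(),
                          heterozygosity = numeric()))
  }
  n_chr2 <- 2L * ncol(pop$origin_a)
  cell <- cell_index(ls, pop$row, pop$col)
  extra <- rowsum(extra_chromosomes(pop, species), cell)
  nbird <- rowsum(rep(1L, nrow(pop)), cell)
  cells <- as.integer(rownames(extra))
  nc <- attr(ls, "n_cols")
  tibble::tibble(
    row = (cells - 1L) %/% nc + 1L,
    col = (cells - 1L) %% nc + 1L,
    n = as.integer(nbird[, 1]),
    heterozygosity = 100 * extra[, 1] / (n_chr2 * nbird[, 1])
  )
}

#' Per-patch adult density map
#'
#' Adult counts of one species for every non-nodata patch (zero where
#' absent); the counts sum to the species' population size.
#'
#' @inheritParams patch_heterozygosity
#' @return Tibble with columns `row`, `col`, `n`.
#' @export
density_map <- function(population, ls, species = "silvanus") {
  out <- tibble::tibble(row = ls$row, col = ls$col,
                        n = 0L)[!is.na(ls$agc), ]
  pop <- population[population$species == species, ]
  if (nrow(pop) > 0) {
    cell <- cell_index(ls, pop$row, pop$col)
    cnt <- table(cell)
    idx <- match(as.integer(names(cnt)), cell_index(ls, out$row, out$col))
    out$n[idx] <- as.integer(cnt)
  }
  out
}

#' Fragment-level admixture heterozygosity
#'
#' Heterozygosity of the species' gene pool restricted to the residents of
#' each montane-forest fragment (residence at census time). Uninhabited
#' fragments are reported as missing, not zero.
#'
#' @param population Population tibble.
#' @param fragments Fragment table from [identify_fragments()] (or the
#'   generator's ground truth).
#' @param ls A `zos_landscape`.
#' @param species Species tag.
#' @return Tibble: `fragment`, `area_ha`, `n`, `heterozygosity`.
#' @export
fragment_heterozygosity <- function(population, fragments, ls,
                                    species = "silvanus") {
  pop <- population[population$species == species, ]
  n_chr2 <- if (nrow(pop) > 0) 2L * ncol(pop$origin_a) else 2L
  cell <- if (nrow(pop) > 0) cell_index(ls, pop$row, pop$col) else integer()
  extra <- if (nrow(pop) > 0) extra_chromosomes(pop, species) else numeric()
  purrr::pmap(fragments[, c("fragment", "area_ha", "patches")],
              function(fragment, area_ha, patches) {
    fcells <- cell_index(ls, patches$row, patches$col)
    inside <- cell %in% fcells
    n <- sum(inside)
    tibble::tibble(fragment = fragment, area_ha = area_ha, n = n,
                   heterozygosity = if (n > 0)
                     100 * sum(extra[inside]) / (n_chr2 * n)
                   else NA_real_)
  }) |> purrr::list_rbind()
}

#' Regression of fragment heterozygosity on log fragment area
#'
#' Ordinary least squares of mean fragment heterozygosity (%) on the
#' natural-log-transformed fragment area (ha). Fragments with missing
#' heterozygosity are excluded; at least three defined points are required.
#'
#' @param data Data frame of fragment statistics.
#' @param area,heterozygosity Column names (strings) of area (ha) and
#'   heterozygosity (%).
#' @return A `zos_fragment_fit`: list with `model` (the underlying `lm`),
#'   `slope` (% per ln-ha), `adj_r_squared` and `n`.
#' @export
#' @examples
#' fit <- fragment_regression(taita_fragments, heterozygosity = "mean")
#' fit$slope
fragment_regression <- function(data, area = "area_ha",
                                heterozygosity = "heterozygosity") {
  d <- tibble::tibble(log_area = log(data[[area]]),
                      heterozygosity = data[[heterozygosity]])
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 3) {
    abort("fragment_regression needs at least 3 fragments with defined heterozygosity.")
  }
  m <- lm(heterozygosity ~ log_area, data = d)
  structure(list(model = m,
                 slope = unname(coef(m)[["log_area"]]),
                 adj_r_squared = summary(m)$adj.r.squared,
                 n = nrow(d)),
            class = "zos_fragment_fit")
}

#' @export
print.zos_fragment_fit <- function(x, ...) {
  cat("<zos_fragment_fit> slope = ", format(x$slope, digits = 3),
      " % per ln-ha, adj R^2 = ", format(x$adj_r_squared, digits = 3),
      " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Tidy the fragment-area regression
#' @param x A `zos_fragment_fit`.
#' @param ... Passed to the `lm` tidier.
#' @return Coefficient-level tibble.
#' @export
tidy.zos_fragment_fit <- function(x, ...) {
  if (requireNamespace("broom", quietly = TRUE)) {
    broom::tidy(x$model, ...)
  } else {
    co <- summary(x$model)$coefficients
    tibble::tibble(term = rownames(co), estimate = co[, 1],
                   std.error = co[, 2], statistic = co[, 3],
                   p.value = co[, 4])
  }
}

#' Model-level summary of the fragment-area regression
#' @param x A `zos_fragment_fit`.
#' @param ... Unused.
#' @return One-row tibble with `slope`, `adj.r.squared`, `n`.
#' @export
glance.zos_fragment_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, adj.r.squared = x$adj_r_squared, n = x$n)
}

#' Write a simulation result to disk
#'
#' Writes the per-year records as a tidy CSV, the final replicate's
#' population snapshot as a CSV, the focal species' final density and
#' heterozygosity maps as text grids in the raster dialect of
#' [write_agc_grid()], and a run manifest (configuration echo and seed) as
#' YAML.
#'
#' @param result A `zos_result` (with `keep_final = TRUE` for snapshot and
#'   maps).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(result), file.path(dir, "years.csv"))
  cfg <- result$config
  manifest <- list(
    scenario = if (is.character(cfg$scenario)) cfg$scenario else cfg$scenario$name,
    h = cfg$h, years = cfg$years, replicates = cfg$replicates,
    genes_per_chromosome = cfg$genes_per_chromosome,
    mutation = cfg$mutation[c("enabled", "rate")],
    seed = cfg$seed, focal = cfg$focal,
    species = purrr::map(cfg$species, function(s) {
      c(as.list(s$traits), survival = s$survival,
        list(offspring_dist = s$offspring_dist))
    })
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  if (!is.null(result$fragments)) {
    readr::write_csv(result$fragments, file.path(dir, "fragments.csv"))
  }
  if (!is.null(result$final)) {
    r <- length(result$final)
    pop <- result$final[[r]]
    snap <- tibble::tibble(
      year = cfg$years, replicate = r, bird_id = pop$id,
      species = pop$species, sex = pop$sex, row = pop$row, col = pop$col,
      paired = !is.na(pop$partner),
      agc_optimum = pop$agc_optimum, agc_tolerance = pop$agc_tolerance,
      dispersal_mean = pop$dispersal_mean,
      dispersal_shape = pop$dispersal_shape,
      extraspecific_chromosomes = extra_chromosomes(pop, cfg$focal)
    )
    readr::write_csv(snap, file.path(dir, "final_population.csv"))
    ls <- result$landscape
    dm <- density_map(pop, ls, cfg$focal)
    dmat <- matrix(NA_real_, attr(ls, "n_rows"), attr(ls, "n_cols"))
    dmat[cbind(dm$row, dm$col)] <- dm$n
    write_agc_grid(dmat, file.path(dir, "density_map.txt"))
    ph <- patch_heterozygosity(pop, ls, cfg$focal)
    hmat <- matrix(NA_real_, attr(ls, "n_rows"), attr(ls, "n_cols"))
    hmat[cbind(ph$row, ph$col)] <- round(ph$heterozygosity, 4)
    write_agc_grid(hmat, file.path(dir, "heterozygosity_map.txt"))
  }
  invisible(dir)
}
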