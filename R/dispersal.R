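#' Draw maximum natal dispersal distances
#'
#' Distances come from a heavy-tailed two-parameter kernel: a logistic
#' distribution with location `mean` and scale `shape`, truncated below at
#' one patch length (a disperser always leaves its natal patch). Drawn once
#' per juvenile, the value caps the Euclidean path length of the greedy walk
#' (orthogonal step 1, diagonal step sqrt(2)).
#'
#' @param n Number of draws.
#' @param mean Kernel location, in patch lengths (>= 0).
#' @param shape Kernel scale (> 0). Vectors are recycled over `n`.
#' @return Numeric vector of distances, all >= 1.
#' @export
draw_max_distance <- function(n, mean, shape) {
  stopifnot(all(mean >= 0), all(shape > 0))
  p1 <- plogis(1, location = mean, scale = shape)
  u <- runif(n, min = p1, max = 1)
  d <- qlogis(u, location = rep_len(mean, n), scale = rep_len(shape, n))
  pmax(d, 1)
}

#' One greedy dispersal step
#'
#' Moves to the 8-neighbour (on-grid, non-nodata) patch whose AGC is closest
#' to the bird's AGC optimum; ties are broken uniformly at random. Exactly
#' one uniform deviate is consumed per call, so a path is reproducible from
#' the RNG seed. There is no matrix-avoidance penalty: attraction to the AGC
#' optimum is the only habitat response.
#'
#' @param ls A `zos_landscape`.
#' @param row,col Current position (1-based).
#' @param agc_optimum The mover's AGC optimum.
#' @return List with `row`, `col` (new position) and `step_length` (1 or
#'   sqrt(2)), or `NULL` when the cell has no valid neighbour.
#' @export
sms_step <- function(ls, row, col, agc_optimum) {
  agc <- as.vector(t(landscape_matrix(ls, "agc")))
  nr <- attr(ls, "n_rows"); nc <- attr(ls, "n_cols")
  out <- sms_step_cpp(agc, nr, nc, row - 1L, col - 1L, agc_optimum)
  if (out[1] < 0) return(NULL)
  nrow_ <- out[1] + 1L; ncol_ <- out[2] + 1L
  list(row = nrow_, col = ncol_,
       step_length = if (nrow_ != row && ncol_ != col) sqrt(2) else 1)
}

#' Settlement suitability of a patch
#'
#' A patch is suitable for a disperser iff its AGC is within the bird's
#' tolerance band and either (a) at least two capacity slots are free, so
#' the bird can stake out a territory for a future breeding pair
#' (`"territory"`), or (b) an unpaired opposite-sex resident is present to
#' pair with (`"join"`; the pairing itself is conspecific-always /
#' heterospecific-with-probability-h). A single without a reserved slot is
#' only joinable while the patch has a free slot.
#'
#' @param agc_optimum,agc_tolerance The disperser's habitat traits.
#' @param sex,species The disperser's sex and species tag.
#' @param agc,capacity,slots_used Patch state.
#' @param residents Tibble of the patch's unpaired residents with columns
#'   `sex`, `species`, `weight` (may have zero rows).
#' @return `"join"`, `"territory"` or `"unsuitable"` (joining takes
#'   precedence when a conspecific single is available; otherwise a free
#'   territory is preferred over a heterospecific pairing attempt).
#' @export
settlement_mode <- function(agc_optimum, agc_tolerance, sex, species,
                            agc, capacity, slots_used,
                            residents = NULL) {
  if (is.na(agc) || abs(agc - agc_optimum) > agc_tolerance) return("unsuitable")
  if (!is.null(residents) && nrow(residents) > 0) {
    open <- residents$sex != sex &
      (residents$weight == 2L | slots_used < capacity)
    if (any(open & residents$species == species)) return("join")
  }
  if (slots_used + 2 <= capacity) return("territory")
  if (!is.null(residents) && nrow(residents) > 0 &&
      any(residents$sex != sex & residents$species != species &
            (residents$weight == 2L | slots_used < capacity))) {
    return("join")
  }
  "unsuitable"
}

# per-cell used capacity slots from settled birds' weights
slot_counts <- function(population, ls) {
  ncell <- attr(ls, "n_rows") * attr(ls, "n_cols")
  slots <- integer(ncell)
  if (nrow(population) > 0) {
    cell <- cell_index(ls, population$row, population$col)
    agg <- rowsum(as.numeric(population$weight), cell)
    slots[as.integer(rownames(agg))] <- as.integer(agg[, 1])
  }
  slots
}

#' Disperse a cohort of juveniles
#'
#' Each juvenile (processed in random order) draws a maximum distance from
#' its expressed dispersal kernel, then walks greedily via [sms_step()],
#' checking settlement on every newly entered patch: joining an unpaired
#' conspecific single is preferred, then staking out a free territory (two
#' slots), then a heterospecific pairing attempt accepted with probability
#' `h` (a declined attempt continues the walk). Exceeding the drawn distance
#' is death. Birds that settle as territory holders become joinable by later
#' dispersers of the same cohort.
#'
#' @param juveniles Juvenile tibble from [reproduce_pairs()].
#' @param population Settled population tibble (residents).
#' @param ls A `zos_landscape`.
#' @param h Hybridization propensity in `[0, 1]`.
#' @return List with `settled` (juveniles that settled, population format),
#'   `population` (residents with new pair links), and `log` (one row per
#'   juvenile: `id`, `outcome`, `row`, `col`, `steps`, `distance`).
#' @export
disperse_juveniles <- function(juveniles, population, ls, h = 0) {
  nr <- attr(ls, "n_rows"); nc <- attr(ls, "n_cols")
  empty_log <- tibble::tibble(id = integer(), outcome = character(),
                              row = integer(), col = integer(),
                              steps = integer(), distance = numeric())
  if (nrow(juveniles) == 0) {
    return(list(settled = juveniles, population = population, log = empty_log))
  }
  tags <- zos_species_tags
  extra <- setdiff(unique(c(population$species, juveniles$species)), tags)
  tags <- c(tags, extra)

  ord <- sample.int(nrow(juveniles))
  juv <- vctrs::vec_slice(juveniles, ord)
  maxd <- draw_max_distance(nrow(juv), juv$dispersal_mean, juv$dispersal_shape)

  singles <- which(is.na(population$partner))
  agc <- as.vector(t(landscape_matrix(ls, "agc")))
  res <- disperse_cpp(
    agc, as.integer(ls$capacity), slot_counts(population, ls), nr, nc,
    res_cell = cell_index(ls, population$row[singles], population$col[singles]) - 1L,
    res_sex = as.integer(population$sex[singles] == "M") + 1L,
    res_species = match(population$species[singles], tags),
    res_weight = as.integer(population$weight[singles]),
    juv_cell = cell_index(ls, juv$row, juv$col) - 1L,
    juv_sex = as.integer(juv$sex == "M") + 1L,
    juv_species = match(juv$species, tags),
    juv_o = juv$agc_optimum, juv_tau = juv$agc_tolerance,
    juv_maxd = maxd, h = h
  )

  settled_i <- which(res$status > 0)
  juv_row <- juv$row; juv_col <- juv$col
  juv_weight <- juv$weight; juv_partner <- juv$partner; juv_id <- juv$id
  juv_row[settled_i] <- res$settle_cell[settled_i] %/% nc + 1L
  juv_col[settled_i] <- res$settle_cell[settled_i] %% nc + 1L
  juv_weight[settled_i] <- c(2L, 1L)[res$status[settled_i]]

  # resolve join partners: positive = index into `singles`, negative = an
  # earlier juvenile of this cohort that settled as a territory holder.
  # each single is joined at most once, so this is conflict-free.
  joins <- which(res$status == 2L)
  src <- res$partner_src[joins]
  jp <- joins[src > 0]
  if (length(jp) > 0) {
    pr <- singles[src[src > 0]]
    pop_partner <- population$partner; pop_weight <- population$weight
    pop_partner[pr] <- juv_id[jp]
    pop_weight[pr] <- 1L
    population$partner <- pop_partner
    population$weight <- pop_weight
    juv_partner[jp] <- population$id[pr]
  }
  jn <- joins[src < 0]
  if (length(jn) > 0) {
    mate <- -src[src < 0]
    juv_partner[jn] <- juv_id[mate]
    juv_partner[mate] <- juv_id[jn]
    juv_weight[mate] <- 1L
  }
  juv$row <- juv_row; juv$col <- juv_col
  juv$weight <- juv_weight; juv$partner <- juv_partner

  log <- tibble::tibble(
    id = juv$id,
    outcome = c("dead", "territory", "join")[res$status + 1L],
    row = ifelse(res$status > 0, juv$row, NA_integer_),
    col = ifelse(res$status > 0, juv$col, NA_integer_),
    steps = res$steps, distance = res$distance
  )
  list(settled = vctrs::vec_slice(juv, settled_i),
       population = population, log = log)
}
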