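#' Species parameter set
#'
#' Founder trait values and demographic rates of one species. The annual
#' survival default of 0.875 follows from a mean life expectancy of about
#' eight years under geometric lifetimes (1 / (1 - s) = 8). The offspring
#' distribution over broods of 0, 1 or 2 fledged young defaults to uniform
#' (mean 1), which folds juvenile mortality into fecundity.
#'
#' @param tag Species tag, e.g. `"silvanus"`.
#' @param agc_optimum,agc_tolerance Habitat adaptation (Mg C ha^-1); a patch
#'   is within the species' band iff `|agc - optimum| <= tolerance`.
#' @param dispersal_mean,dispersal_shape Location and scale of the juvenile
#'   dispersal kernel, in patch lengths.
#' @param survival Annual survival probability in `(0, 1]`.
#' @param offspring_dist Probabilities of 0, 1 and 2 offspring (length 3,
#'   sums to 1).
#' @return A `zos_species` object.
#' @export
species_params <- function(tag, agc_optimum, agc_tolerance,
                           dispersal_mean, dispersal_shape,
                           survival = 0.875,
                           offspring_dist = c(1, 1, 1) / 3) {
  stopifnot(agc_tolerance >= 0, dispersal_mean >= 0, dispersal_shape > 0,
            survival > 0, survival <= 1, length(offspring_dist) == 3,
            all(offspring_dist >= 0))
  offspring_dist <- offspring_dist / sum(offspring_dist)
  structure(list(
    tag = tag,
    traits = c(agc_optimum = agc_optimum, agc_tolerance = agc_tolerance,
               dispersal_mean = dispersal_mean, dispersal_shape = dispersal_shape),
    survival = survival,
    offspring_dist = offspring_dist
  ), class = "zos_species")
}

#' Default species parameterization
#'
#' The montane habitat specialist *Zosterops silvanus* (AGC band 90-270
#' Mg C ha^-1, strong disperser) and the lowland generalist
#' *Z. flavilateralis* (band 3-97, weaker disperser). Dispersal kernel
#' defaults are calibration values chosen so that inter-fragment distances on
#' a Taita-like synthetic map are within the specialist's reach.
#'
#' @return Named list of two [species_params()] objects.
#' @export
default_species <- function() {
  list(
    silvanus = species_params("silvanus", 180, 90, 30, 10),
    flavilateralis = species_params("flavilateralis", 50, 47, 15, 5)
  )
}

pop_columns <- function(g = 1L) {
  n_chr <- 4L / g
  tibble::tibble(
    id = integer(), species = character(), sex = character(),
    row = integer(), col = integer(), partner = integer(), age = integer(),
    weight = integer(),
    agc_optimum = numeric(), agc_tolerance = numeric(),
    dispersal_mean = numeric(), dispersal_shape = numeric(),
    allele_a = matrix(numeric(), 0, 4, dimnames = list(NULL, zos_traits)),
    allele_b = matrix(numeric(), 0, 4, dimnames = list(NULL, zos_traits)),
    origin_a = matrix(integer(), 0, n_chr),
    origin_b = matrix(integer(), 0, n_chr)
  )
}

#' Extract the genome set of a population
#'
#' @param population A population tibble.
#' @return A [zos_genomes] set in the population's row order.
#' @export
population_genomes <- function(population) {
  g <- 4L / ncol(population$origin_a)
  new_genomes(population$allele_a, population$allele_b,
              population$origin_a, population$origin_b, g)
}

# build bird rows from a genome set + metadata vectors
birds_from_genomes <- function(ids, species, sex, row, col, genomes,
                               age = 0L, weight = NA_integer_,
                               partner = NA_integer_) {
  traits <- express_traits(genomes)
  n <- length(ids)
  tibble::new_tibble(list(
    id = as.integer(ids), species = rep_len(species, n),
    sex = rep_len(sex, n),
    row = rep_len(as.integer(row), n), col = rep_len(as.integer(col), n),
    partner = rep_len(as.integer(partner), n),
    age = rep_len(as.integer(age), n),
    weight = rep_len(as.integer(weight), n),
    agc_optimum = traits$agc_optimum, agc_tolerance = traits$agc_tolerance,
    dispersal_mean = traits$dispersal_mean,
    dispersal_shape = traits$dispersal_shape,
    allele_a = genomes$allele_a, allele_b = genomes$allele_b,
    origin_a = genomes$origin_a, origin_b = genomes$origin_b
  ), nrow = n)
}

# random within-group ranks for (key, sex) groups; used to pair males and
# females of equal rank
group_rank <- function(key) {
  u <- runif(length(key))
  ord <- order(key, u)
  runs <- rle(key[ord])$lengths
  rk <- integer(length(key))
  rk[ord] <- sequence(runs)
  rk
}

#' Initialize a founder population on a landscape
#'
#' Every patch whose AGC lies within a species' tolerance band receives a
#' uniform random number of homozygous founders of that species, between 0
#' and the patch's remaining carrying capacity (species draw in random order
#' per patch, so neither is systematically favoured where bands overlap).
#' Founders are then put through one settlement-style pairing pass within
#' their patch: opposite-sex conspecifics pair up, and remaining
#' heterospecific pairs form with probability `h` each, mirroring the pairing
#' rule used at settlement. Without this pass no pair could ever form, since
#' the annual cycle creates pairs only when dispersers join residents.
#'
#' @param ls A `zos_landscape`.
#' @param species List of [species_params()] (default [default_species()]).
#' @param h Hybridization propensity used for founder pairing.
#' @param genes_per_chromosome Genome layout (1, 2 or 4 genes per chromosome).
#' @param pair_founders Set `FALSE` to leave all founders unpaired.
#' @return A population tibble (one row per bird).
#' @export
initialize_population <- function(ls, species = default_species(), h = 0,
                                  genes_per_chromosome = 1,
                                  pair_founders = TRUE) {
  g <- validate_gpc(genes_per_chromosome)
  k <- length(species)
  np <- nrow(ls)
  rem <- ls$capacity
  rem[is.na(ls$agc)] <- 0L
  counts <- matrix(0L, np, k)
  # per-patch random species order: rank k random priorities within each row
  if (k == 1) {
    rk <- matrix(1L, np, 1)
  } else if (k == 2) {
    first <- runif(np) < 0.5
    rk <- cbind(ifelse(first, 1L, 2L), ifelse(first, 2L, 1L))
  } else {
    rk <- t(apply(matrix(runif(np * k), np, k), 1, rank))
  }
  for (r in seq_len(k)) {
    for (s in seq_len(k)) {
      sp <- species[[s]]
      elig <- !is.na(ls$agc) &
        abs(ls$agc - sp$traits[["agc_optimum"]]) <= sp$traits[["agc_tolerance"]] &
        rk[, s] == r & rem > 0
      if (!any(elig)) next
      draw <- as.integer(floor(runif(sum(elig)) * (rem[elig] + 1L)))
      counts[elig, s] <- draw
      rem[elig] <- rem[elig] - draw
    }
  }
  parts <- vector("list", k)
  next_id <- 1L
  for (s in seq_len(k)) {
    sp <- species[[s]]
    n_s <- sum(counts[, s])
    if (n_s == 0) { parts[[s]] <- pop_columns(g); next }
    patch_idx <- rep(seq_len(np), counts[, s])
    gn <- founder_genomes(n_s, sp$traits, sp$tag, g)
    parts[[s]] <- birds_from_genomes(
      ids = next_id:(next_id + n_s - 1L), species = sp$tag,
      sex = c("F", "M")[1L + (runif(n_s) >= 0.5)],
      row = ls$row[patch_idx], col = ls$col[patch_idx], genomes = gn,
      age = 1L, weight = 1L
    )
    next_id <- next_id + n_s
  }
  pop <- dplyr::bind_rows(parts)
  if (pair_founders && nrow(pop) > 0) pop <- pair_founder_population(pop, ls, h)
  pop
}

# settlement-style pairing among co-resident founders
pair_founder_population <- function(pop, ls, h) {
  cell <- cell_index(ls, pop$row, pop$col)
  spid <- match(pop$species, unique(pop$species))
  key <- cell * (max(spid) + 1L) + spid
  # conspecific pairing: male rank j pairs female rank j within (cell, species)
  is_f <- pop$sex == "F"
  rk <- integer(nrow(pop))
  rk[is_f] <- group_rank(key[is_f])
  rk[!is_f] <- group_rank(key[!is_f])
  big <- max(rk) + 1L
  pair_key <- key * big + rk
  m_idx <- which(!is_f)
  f_idx <- which(is_f)
  j <- match(pair_key[m_idx], pair_key[f_idx])
  matched <- !is.na(j)
  pop$partner[m_idx[matched]] <- pop$id[f_idx[j[matched]]]
  pop$partner[f_idx[j[matched]]] <- pop$id[m_idx[matched]]
  if (h > 0 && length(unique(pop$species)) > 1) {
    # heterospecific leftovers: only cells holding unpaired birds of both
    # species (band-overlap cells) need a look
    un <- which(is.na(pop$partner))
    both <- intersect(unique(cell[un][spid[un] == 1L]),
                      unique(cell[un][spid[un] == 2L]))
    for (cl in both) {
      here <- un[cell[un] == cl]
      repeat {
        mm <- here[pop$sex[here] == "M" & is.na(pop$partner[here])]
        ff <- here[pop$sex[here] == "F" & is.na(pop$partner[here])]
        cand <- expand.grid(m = mm, f = ff)
        cand <- cand[pop$species[cand$m] != pop$species[cand$f], , drop = FALSE]
        if (nrow(cand) == 0) break
        pick <- cand[sample.int(nrow(cand), 1), ]
        if (runif(1) < h) {
          pop$partner[pick$m] <- pop$id[pick$f]
          pop$partner[pick$f] <- pop$id[pick$m]
        } else break
      }
    }
  }
  pop
}

#' Annual survival
#'
#' Each bird independently survives the year with its species' fixed,
#' density-independent survival probability. Dead birds vacate their slot;
#' a surviving partner is widowed: it stays on the pair territory (two
#' capacity slots, one reserved for a future mate found by an arriving
#' disperser) and becomes partner-less.
#'
#' @param population Population tibble.
#' @param survival Scalar probability, or named vector by species tag.
#' @return The surviving population.
#' @export
annual_survival <- function(population, survival = 0.875) {
  n <- nrow(population)
  if (n == 0) return(population)
  s <- if (length(survival) > 1) unname(survival[population$species])
       else rep(survival, n)
  stopifnot(all(s > 0 & s <= 1))
  alive <- runif(n) < s
  dead_ids <- population$id[!alive]
  widowed <- alive & population$partner %in% dead_ids
  population$weight[widowed] <- 2L
  population$partner[widowed] <- NA_integer_
  vctrs::vec_slice(population, alive)
}

#' Pairing acceptance rule
#'
#' Conspecific candidates are always accepted; a heterospecific candidate is
#' accepted with the hybridization propensity `h`. Vectorized.
#'
#' @param species_a,species_b Species tags of the two birds.
#' @param h Hybridization propensity in `[0, 1]`.
#' @return Logical vector of acceptances.
#' @export
pair_accepted <- function(species_a, species_b, h) {
  conspecific <- species_a == species_b
  conspecific | (runif(length(conspecific)) < h)
}

#' Form a breeding pair between two co-resident birds
#'
#' Applies [pair_accepted()] to an unpaired, opposite-sex, co-located pair of
#' birds and, on acceptance, links them symmetrically.
#'
#' @param population Population tibble.
#' @param resident_id,candidate_id Bird ids.
#' @param h Hybridization propensity.
#' @return List with `population` (updated) and `paired` (logical).
#' @export
form_pair <- function(population, resident_id, candidate_id, h = 0) {
  i <- match(resident_id, population$id)
  j <- match(candidate_id, population$id)
  if (is.na(i) || is.na(j)) abort("Unknown bird id.")
  if (!is.na(population$partner[i]) || !is.na(population$partner[j])) {
    abort("Both birds must be unpaired.")
  }
  if (population$sex[i] == population$sex[j]) {
    abort("Pair formation requires opposite sexes.")
  }
  if (population$row[i] != population$row[j] ||
      population$col[i] != population$col[j]) {
    abort("Pair formation requires co-located birds.")
  }
  ok <- pair_accepted(population$species[i], population$species[j], h)
  if (ok) {
    population$partner[i] <- population$id[j]
    population$partner[j] <- population$id[i]
    population$weight[c(i, j)] <- 1L
  }
  list(population = population, paired = ok)
}

#' Assign a species label to offspring
#'
#' Offspring of conspecific parents inherit the common tag. Hybrid offspring
#' are assigned to the parent whose expressed phenotype is closer in
#' normalized trait space: each trait difference is scaled by the founder
#' inter-species difference for that trait, so all four traits contribute
#' comparably. Exact ties are resolved uniformly at random.
#'
#' @param offspring_traits Tibble/data frame with the four trait columns
#'   (one row per offspring).
#' @param mother_species,father_species Parent species tags (recycled).
#' @param mother_traits,father_traits Parent expressed traits, same shape as
#'   `offspring_traits`.
#' @param trait_scale Named per-trait scale; defaults to the founder
#'   differences of [default_species()].
#' @return Character vector of species tags.
#' @export
assign_offspring_species <- function(offspring_traits, mother_species,
                                     father_species, mother_traits,
                                     father_traits,
                                     trait_scale = NULL) {
  n <- nrow(offspring_traits)
  mother_species <- rep_len(mother_species, n)
  father_species <- rep_len(father_species, n)
  out <- mother_species
  hyb <- mother_species != father_species
  if (!any(hyb)) return(out)
  if (is.null(trait_scale)) {
    sp <- default_species()
    trait_scale <- abs(sp[[1]]$traits - sp[[2]]$traits)[zos_traits]
  }
  sc <- matrix(unname(trait_scale[zos_traits]), nrow = sum(hyb), ncol = 4,
               byrow = TRUE)
  om <- as.matrix(offspring_traits[hyb, zos_traits])
  dm <- rowSums(((om - as.matrix(mother_traits[hyb, zos_traits])) / sc)^2)
  df <- rowSums(((om - as.matrix(father_traits[hyb, zos_traits])) / sc)^2)
  tie <- abs(dm - df) < 1e-12
  closer_mother <- dm < df
  closer_mother[tie] <- runif(sum(tie)) < 0.5
  out[hyb] <- ifelse(closer_mother, mother_species[hyb], father_species[hyb])
  out
}

#' Reproduce all intact breeding pairs
#'
#' Each pair draws a brood of 0, 1 or 2 offspring from the mother's species'
#' offspring distribution. Every offspring genome is the fusion of one
#' meiotic gamete from each parent, its sex is random, its species follows
#' [assign_offspring_species()], and it starts unsettled at the natal patch
#' (juveniles do not count against carrying capacity until settlement).
#'
#' @param population Population tibble.
#' @param species Named list of [species_params()] covering all tags present.
#' @param mutation Optional list `list(rate =, sd =)`; when given, juvenile
#'   genomes are mutated before trait expression.
#' @param next_id First id to assign to juveniles; defaults past the current
#'   maximum.
#' @return Tibble of juveniles (possibly empty), in population format with
#'   `weight = NA` marking them unsettled.
#' @export
reproduce_pairs <- function(population, species = default_species(),
                            mutation = NULL, next_id = NULL) {
  g <- 4L / ncol(population$origin_a)
  if (nrow(population) == 0) return(pop_columns(g))
  prow <- match(population$partner, population$id)
  mothers <- which(!is.na(prow) & population$sex == "F")
  if (length(mothers) == 0) return(pop_columns(g))
  fathers <- prow[mothers]
  dist3 <- vapply(species, function(s) s$offspring_dist, numeric(3))
  pd <- t(dist3[, match(population$species[mothers], names(species)), drop = FALSE])
  u <- runif(length(mothers))
  brood <- as.integer((u > pd[, 1]) + (u > pd[, 1] + pd[, 2]))
  keep <- brood > 0
  if (!any(keep)) return(pop_columns(g))
  mom_idx <- rep(mothers[keep], brood[keep])
  dad_idx <- rep(fathers[keep], brood[keep])
  gn <- population_genomes(population)
  child <- fuse(meiosis(genomes_subset(gn, mom_idx)),
                meiosis(genomes_subset(gn, dad_idx)))
  if (!is.null(mutation) && isTRUE(mutation$enabled %||% TRUE)) {
    child <- mutate_genomes(child, mutation$rate, mutation$sd)
  }
  n_off <- length(mom_idx)
  traits <- express_traits(child)
  tags <- assign_offspring_species(
    traits,
    mother_species = population$species[mom_idx],
    father_species = population$species[dad_idx],
    mother_traits = trait_block(population, mom_idx),
    father_traits = trait_block(population, dad_idx),
    trait_scale = founder_trait_scale(species)
  )
  if (is.null(next_id)) next_id <- max(population$id) + 1L
  birds_from_genomes(
    ids = next_id:(next_id + n_off - 1L), species = tags,
    sex = c("F", "M")[1L + (runif(n_off) >= 0.5)],
    row = population$row[mom_idx], col = population$col[mom_idx],
    genomes = child, age = 0L, weight = NA_integer_
  )
}

trait_block <- function(population, idx) {
  tibble::tibble(
    agc_optimum = population$agc_optimum[idx],
    agc_tolerance = population$agc_tolerance[idx],
    dispersal_mean = population$dispersal_mean[idx],
    dispersal_shape = population$dispersal_shape[idx]
  )
}

founder_trait_scale <- function(species) {
  if (length(species) < 2) return(NULL)
  abs(species[[1]]$traits - species[[2]]$traits)[zos_traits]
}
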