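#' Genome sets
#'
#' Diploid genomes of quantitative-trait alleles. Every bird carries, for each
#' of the four traits (`agc_optimum`, `agc_tolerance`, `dispersal_mean`,
#' `dispersal_shape`), one maternal-side and one paternal-side allele; alleles
#' sit on chromosomes that carry `genes_per_chromosome` consecutive traits and
#' an immutable species-of-origin tag. With the default of one gene per
#' chromosome a haploid set has four chromosomes; higher values model genetic
#' linkage (4 traits allow 1, 2 or 4 genes per chromosome).
#'
#' A genome set stores `n` genomes column-wise for speed:
#' `allele_a`/`allele_b` are `n x 4` numeric matrices (one column per trait)
#' and `origin_a`/`origin_b` are `n x n_chromosomes` integer matrices of
#' species-tag indices (1 = silvanus, 2 = flavilateralis by default).
#'
#' @name zos_genomes
NULL

new_genomes <- function(allele_a, allele_b, origin_a, origin_b, g,
                        species_tags = zos_species_tags) {
  structure(list(allele_a = allele_a, allele_b = allele_b,
                 origin_a = origin_a, origin_b = origin_b,
                 genes_per_chromosome = as.integer(g),
                 species_tags = species_tags),
            class = "zos_genomes")
}

#' @export
print.zos_genomes <- function(x, ...) {
  cat("<zos_genomes> ", nrow(x$allele_a), " genomes, ",
      ncol(x$origin_a), " chromosome pair(s), ",
      x$genes_per_chromosome, " gene(s) per chromosome\n", sep = "")
  invisible(x)
}

#' Number of genomes in a genome set
#' @param genomes A `zos_genomes` object.
#' @return Integer count.
#' @export
n_genomes <- function(genomes) nrow(genomes$allele_a)

# chromosome carrying trait t (1..4) under g genes per chromosome
chromosome_of_trait <- function(g) rep(seq_len(4L / g), each = g)

validate_gpc <- function(g) {
  if (!g %in% c(1L, 2L, 4L)) {
    abort("`genes_per_chromosome` must be 1, 2 or 4 (four traits).")
  }
  as.integer(g)
}

#' Create homozygous founder genomes
#'
#' Founders are homozygous for their species' trait values and every
#' chromosome is tagged with the founder species.
#'
#' @param n Number of genomes.
#' @param traits Named numeric vector with entries `agc_optimum`,
#'   `agc_tolerance`, `dispersal_mean`, `dispersal_shape`.
#' @param species Founder species tag.
#' @param genes_per_chromosome Genes per chromosome (1, 2 or 4).
#' @param species_tags Tag universe; `species` must be one of them.
#' @return A [zos_genomes] set.
#' @export
#' @examples
#' g <- founder_genomes(2, c(agc_optimum = 180, agc_tolerance = 90,
#'                           dispersal_mean = 30, dispersal_shape = 10),
#'                      "silvanus")
#' express_traits(g)
founder_genomes <- function(n, traits, species, genes_per_chromosome = 1,
                            species_tags = zos_species_tags) {
  g <- validate_gpc(genes_per_chromosome)
  if (!all(zos_traits %in% names(traits))) {
    abort(paste0("`traits` must name all of: ", paste(zos_traits, collapse = ", ")))
  }
  sp <- match(species, species_tags)
  if (is.na(sp)) abort(paste0("Unknown species tag '", species, "'."))
  vals <- unname(traits[zos_traits])
  al <- matrix(rep(vals, each = n), nrow = n, dimnames = list(NULL, zos_traits))
  n_chr <- 4L / g
  org <- matrix(sp, nrow = n, ncol = n_chr)
  new_genomes(al, al, org, org, g, species_tags)
}

#' Express traits from a genome set
#'
#' Each trait is the arithmetic mean of its two allele values.
#'
#' @param genomes A [zos_genomes] set.
#' @return Tibble with one row per genome and one column per trait.
#' @export
express_traits <- function(genomes) {
  m <- (genomes$allele_a + genomes$allele_b) / 2
  tibble::new_tibble(list(agc_optimum = unname(m[, 1L]),
                          agc_tolerance = unname(m[, 2L]),
                          dispersal_mean = unname(m[, 3L]),
                          dispersal_shape = unname(m[, 4L])),
                     nrow = nrow(m))
}

#' Meiosis: draw one gamete per genome
#'
#' For each homolog pair one whole chromosome is chosen with probability 1/2,
#' independently across pairs (independent assortment; there is no
#' intra-chromosome crossover, so linkage is modelled purely by gene
#' co-location). Origin tags travel with their chromosome.
#'
#' @param genomes A [zos_genomes] set.
#' @return A gamete set: list with `allele` (`n x 4`), `origin`
#'   (`n x n_chromosomes`), `genes_per_chromosome`, `species_tags`.
#' @export
meiosis <- function(genomes) {
  n <- n_genomes(genomes)
  g <- genomes$genes_per_chromosome
  n_chr <- 4L / g
  pick_b <- matrix(runif(n * n_chr) < 0.5, nrow = n, ncol = n_chr)
  chr_of <- chromosome_of_trait(g)
  pick_b_trait <- pick_b[, chr_of, drop = FALSE]
  allele <- ifelse(pick_b_trait, genomes$allele_b, genomes$allele_a)
  dim(allele) <- c(n, 4L)
  colnames(allele) <- zos_traits
  origin <- ifelse(pick_b, genomes$origin_b, genomes$origin_a)
  dim(origin) <- c(n, n_chr)
  list(allele = allele, origin = origin,
       genes_per_chromosome = g, species_tags = genomes$species_tags)
}

#' Fuse two gamete sets into diploid genomes
#'
#' Pairs the i-th chromosome of each gamete; gamete layouts must match.
#'
#' @param gamete_a,gamete_b Gamete sets from [meiosis()], equal length.
#' @return A [zos_genomes] set.
#' @export
fuse <- function(gamete_a, gamete_b) {
  if (gamete_a$genes_per_chromosome != gamete_b$genes_per_chromosome ||
      nrow(gamete_a$allele) != nrow(gamete_b$allele)) {
    abort("Gamete layouts differ; cannot fuse.")
  }
  new_genomes(gamete_a$allele, gamete_b$allele,
              gamete_a$origin, gamete_b$origin,
              gamete_a$genes_per_chromosome, gamete_a$species_tags)
}

#' Default mutation effect standard deviations
#'
#' 5% of the founder inter-species trait difference per trait, a calibration
#' default for the exploratory mutation variant.
#'
#' @param species List of two [species_params()] objects.
#' @return Named numeric vector over the four traits.
#' @export
default_mutation_sd <- function(species = default_species()) {
  a <- species[[1]]$traits[zos_traits]
  b <- species[[2]]$traits[zos_traits]
  0.05 * abs(a - b)
}

#' Mutate genomes
#'
#' Each allele is independently perturbed with probability `rate` by a
#' zero-mean Gaussian with the trait's `sd`. Non-negative traits (all but
#' `agc_optimum` may not go below zero) are floored at zero. Origin tags are
#' untouched.
#'
#' @param genomes A [zos_genomes] set.
#' @param rate Per-allele mutation probability in `[0, 1]`.
#' @param sd Effect standard deviation; scalar or named per-trait vector.
#' @return The mutated [zos_genomes] set.
#' @export
mutate_genomes <- function(genomes, rate, sd) {
  stopifnot(rate >= 0, rate <= 1, all(sd >= 0))
  if (rate == 0 || all(sd == 0)) return(genomes)
  n <- n_genomes(genomes)
  if (n == 0) return(genomes)
  if (length(sd) > 1) sd <- unname(sd[zos_traits])
  sd_m <- matrix(sd, nrow = n, ncol = 4L, byrow = length(sd) > 1)
  floor0 <- zos_traits != "agc_optimum"
  for (side in c("allele_a", "allele_b")) {
    hit <- matrix(runif(n * 4L) < rate, n, 4L)
    eff <- matrix(0, n, 4L)
    k <- sum(hit)
    if (k > 0) eff[hit] <- rnorm(k, 0, sd_m[hit])
    m <- genomes[[side]] + eff
    m[, floor0] <- pmax(m[, floor0, drop = FALSE], 0)
    genomes[[side]] <- m
  }
  genomes
}

#' Extraspecific chromosome fraction (admixture heterozygosity)
#'
#' The percentage of chromosomes in a set of genomes whose founder origin is
#' not the given species: the gene-pool admixture statistic of the model
#' (distinct from locus-level heterozygosity).
#'
#' @param genomes A [zos_genomes] set (the gene pool, e.g. all genomes of
#'   birds labelled `species`).
#' @param species Species tag whose gene pool is examined.
#' @return Percentage in `[0, 100]`; `NA_real_` for an empty set (undefined,
#'   deliberately not 0).
#' @export
extraspecific_fraction <- function(genomes, species = "silvanus") {
  n <- n_genomes(genomes)
  if (n == 0) return(NA_real_)
  sp <- match(species, genomes$species_tags)
  if (is.na(sp)) abort(paste0("Unknown species tag '", species, "'."))
  total <- 2L * ncol(genomes$origin_a) * n
  extra <- sum(genomes$origin_a != sp) + sum(genomes$origin_b != sp)
  100 * extra / total
}

# subset a genome set by index (with repetition allowed)
genomes_subset <- function(genomes, i) {
  new_genomes(genomes$allele_a[i, , drop = FALSE],
              genomes$allele_b[i, , drop = FALSE],
              genomes$origin_a[i, , drop = FALSE],
              genomes$origin_b[i, , drop = FALSE],
              genomes$genes_per_chromosome, genomes$species_tags)
}

genomes_bind <- function(a, b) {
  stopifnot(a$genes_per_chromosome == b$genes_per_chromosome)
  new_genomes(rbind(a$allele_a, b$allele_a), rbind(a$allele_b, b$allele_b),
              rbind(a$origin_a, b$origin_a), rbind(a$origin_b, b$origin_b),
              a$genes_per_chromosome, a$species_tags)
}

#' Tidy genome dump of a population
#'
#' Long-format genome table for debugging and downstream analysis: one row
#' per (bird, homolog, trait).
#'
#' @param population A `zos_population` tibble.
#' @return Tibble with columns `bird_id`, `pair_index`, `homolog` (0/1),
#'   `origin`, `trait_id`, `allele_value`.
#' @export
genome_table <- function(population) {
  gn <- population_genomes(population)
  n <- n_genomes(gn)
  g <- gn$genes_per_chromosome
  chr_of <- chromosome_of_trait(g)
  one_side <- function(homolog, al, org) {
    tibble::tibble(
      bird_id = rep(population$id, times = 4L),
      pair_index = rep(chr_of, each = n),
      homolog = homolog,
      origin = gn$species_tags[as.vector(org[, chr_of, drop = FALSE])],
      trait_id = rep(zos_traits, each = n),
      allele_value = as.vector(al)
    )
  }
  dplyr::bind_rows(one_side(0L, gn$allele_a, gn$origin_a),
                   one_side(1L, gn$allele_b, gn$origin_b)) |>
    dplyr::arrange(.data$bird_id, .data$pair_index, .data$homolog)
}
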