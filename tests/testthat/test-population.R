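test_that("initialization respects tolerance bands and carrying capacity", {
  set.seed(2)
  # AGC 150: silvanus only (150 in [90,270], not in [3,97])
  ls <- flat_landscape(150, 4, 4)
  pop <- initialize_population(ls, pair_founders = FALSE)
  expect_true(all(pop$species == "silvanus"))
  per_patch <- table(paste(pop$row, pop$col))
  expect_true(all(per_patch <= 8))

  # AGC 300: outside both bands
  expect_equal(nrow(initialize_population(flat_landscape(300, 4, 4))), 0)

  # AGC 95: both species eligible, joint total within capacity
  set.seed(3)
  found_both <- FALSE
  for (i in 1:20) {
    p <- initialize_population(flat_landscape(95, 5, 5), pair_founders = FALSE)
    counts <- tapply(p$id, paste(p$row, p$col), length)
    expect_true(all(counts <= 8))
    if (length(unique(p$species)) == 2) found_both <- TRUE
  }
  expect_true(found_both)
})

test_that("founder pairing links opposite-sex conspecifics symmetrically", {
  set.seed(6)
  ls <- flat_landscape(150, 6, 6)
  pop <- initialize_population(ls, h = 0)
  paired <- pop[!is.na(pop$partner), ]
  if (nrow(paired) > 0) {
    mate <- match(paired$partner, pop$id)
    expect_equal(pop$partner[mate], paired$id)        # symmetry
    expect_true(all(pop$sex[mate] != paired$sex))     # heterosexual
    expect_true(all(pop$species[mate] == paired$species)) # conspecific at h=0
    expect_true(all(pop$row[mate] == paired$row &
                      pop$col[mate] == paired$col))   # co-located
  }
})

test_that("survival is an independent Bernoulli thinning with widowing", {
  pop <- founder_population(4)
  expect_identical(nrow(annual_survival(pop, 1)), 4L)

  set.seed(10)
  big <- founder_population(10000)
  kept <- nrow(annual_survival(big, 0.875))
  expect_lt(abs(kept - 8750), 3 * sqrt(10000 * 0.875 * 0.125))

  # a widow loses the partner link and keeps the pair territory (2 slots)
  set.seed(42)
  for (i in 1:50) {
    p2 <- link_pair(founder_population(2), 1, 2)
    s <- annual_survival(p2, 0.5)
    if (nrow(s) == 1) {
      expect_true(is.na(s$partner))
      expect_equal(s$weight, 2L)
    } else if (nrow(s) == 2) {
      expect_false(any(is.na(s$partner)))
    }
  }
})

test_that("simulated mean lifespan under s = 0.875 is eight years", {
  set.seed(1234)
  n <- 10000
  pop <- founder_population(n)
  lifespan <- numeric(0)
  year <- 0
  while (nrow(pop) > 0 && year < 400) {
    year <- year + 1
    survivors <- annual_survival(pop, 0.875)
    died <- setdiff(pop$id, survivors$id)
    lifespan <- c(lifespan, rep(year, length(died)))
    pop <- survivors
  }
  expect_equal(length(lifespan), n)
  se <- sd(lifespan) / sqrt(n)
  expect_lt(abs(mean(lifespan) - 8), 3 * se)
})

test_that("pairing rule: conspecific always, heterospecific with probability h", {
  pop <- dplyr::bind_rows(
    founder_population(1, "silvanus", sex = "F"),
    founder_population(1, "silvanus", sex = "M", id0 = 2L),
    founder_population(1, "flavilateralis", sex = "M", id0 = 3L)
  )
  out <- form_pair(pop, 1L, 2L, h = 0)
  expect_true(out$paired)
  expect_equal(out$population$partner[1], 2L)
  expect_equal(out$population$partner[2], 1L)

  expect_false(form_pair(pop, 1L, 3L, h = 0)$paired)

  expect_error(form_pair(pop, 2L, 3L, h = 1), "opposite sexes")
  expect_error(form_pair(out$population, 1L, 3L, h = 1), "unpaired")

  set.seed(20)
  acc <- pair_accepted(rep("silvanus", 10000), rep("flavilateralis", 10000),
                       h = 0.5)
  expect_lt(abs(sum(acc) - 5000), 150)
  expect_true(all(pair_accepted(rep("a", 100), rep("a", 100), h = 0)))
})

test_that("broods follow the offspring distribution and pure pairs breed true", {
  pop <- link_pair(founder_population(2), 1, 2)
  # point mass at zero: no juveniles
  sp0 <- list(silvanus = species_params("silvanus", 180, 90, 30, 10,
                                        offspring_dist = c(1, 0, 0)),
              flavilateralis = default_species()$flavilateralis)
  expect_equal(nrow(reproduce_pairs(pop, sp0)), 0)

  # uniform default: mean brood 1 over many pairs
  set.seed(14)
  many <- founder_population(18000, sex = rep(c("F", "M"), 9000))
  many <- link_pair(many, seq(1, 18000, 2), seq(2, 18000, 2))
  juv <- reproduce_pairs(many, default_species())
  expect_lt(abs(nrow(juv) / 9000 - 1), 0.03)

  # closure of the pure lineage
  expect_true(all(juv$species == "silvanus"))
  expect_true(all(juv$origin_a == 1L & juv$origin_b == 1L))
  expect_true(all(juv$agc_optimum == 180 & juv$agc_tolerance == 90))
  expect_true(all(is.na(juv$weight)))       # unsettled
  expect_true(all(juv$age == 0L))
  expect_false(any(juv$id %in% many$id))    # fresh ids
})

test_that("hybrid offspring are assigned to the phenotypically closer parent", {
  mt <- tibble::as_tibble(as.list(silvanus_traits()))
  ft <- tibble::as_tibble(as.list(c(agc_optimum = 115, agc_tolerance = 68.5,
                                    dispersal_mean = 22.5,
                                    dispersal_shape = 7.5)))
  # offspring with three silvanus-like traits and one intermediate
  off <- tibble::as_tibble(as.list(c(agc_optimum = 180, agc_tolerance = 90,
                                     dispersal_mean = 30,
                                     dispersal_shape = 7.5)))
  expect_equal(assign_offspring_species(off, "silvanus", "flavilateralis",
                                        mt, ft), "silvanus")
  # mirrored case
  off2 <- tibble::as_tibble(as.list(c(agc_optimum = 115,
                                      agc_tolerance = 68.5,
                                      dispersal_mean = 22.5,
                                      dispersal_shape = 10)))
  expect_equal(assign_offspring_species(off2, "silvanus", "flavilateralis",
                                        mt, ft), "flavilateralis")
  # conspecific parents pass their tag through unchanged
  expect_equal(assign_offspring_species(off, "silvanus", "silvanus", mt, mt),
               "silvanus")
  # an exactly equidistant offspring is assigned at random
  mid <- tibble::as_tibble(as.list(c(agc_optimum = 147.5,
                                     agc_tolerance = 79.25,
                                     dispersal_mean = 26.25,
                                     dispersal_shape = 8.75)))
  set.seed(33)
  draws <- replicate(400, assign_offspring_species(
    mid, "silvanus", "flavilateralis", mt, ft))
  expect_gt(mean(draws == "silvanus"), 0.4)
  expect_lt(mean(draws == "silvanus"), 0.6)
})

test_that("an F1 of pure founders is equidistant and randomly labelled", {
  set.seed(44)
  pop <- dplyr::bind_rows(
    founder_population(1, "silvanus", sex = "F"),
    founder_population(1, "flavilateralis", sex = "M", id0 = 2L)
  )
  pop <- link_pair(pop, 1, 2)
  tags <- character(0)
  for (i in 1:200) {
    juv <- reproduce_pairs(pop, default_species())
    tags <- c(tags, juv$species)
  }
  expect_gt(mean(tags == "silvanus"), 0.4)
  expect_lt(mean(tags == "silvanus"), 0.6)
  # and each F1 contributes 50% heterozygosity to either pool
  f1 <- f1_genomes(1)
  expect_equal(extraspecific_fraction(f1, "silvanus"), 50)
  expect_equal(extraspecific_fraction(f1, "flavilateralis"), 50)
})

test_that("closed gene pools stay pure under h = 0 (exact, all processes)", {
  set.seed(55)
  ls <- generate_landscape(40, 40, fragment_areas = c(9, 4), edge_width = 1,
                           seed = 9, plantation_area = 4)
  cfg <- sim_config(landscape = ls, h = 0, years = 15, replicates = 1,
                    seed = 77)
  res <- run_simulation(cfg)
  expect_true(all(res$years$heterozygosity[res$years$n_adults > 0] == 0))
  fin <- res$final[[1]]
  for (sp in c("silvanus", "flavilateralis")) {
    sub <- fin[fin$species == sp, ]
    if (nrow(sub) > 0) {
      expect_equal(extraspecific_fraction(population_genomes(sub), sp), 0)
    }
  }
})
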