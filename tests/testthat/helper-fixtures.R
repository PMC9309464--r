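# Shared fixtures, built in code.

# a small landscape: one 3x3 forest block (AGC 150) in a woodland matrix
block_landscape <- function(nr = 9, nc = 9, block_agc = 150, matrix_agc = 20) {
  m <- matrix(matrix_agc, nr, nc)
  m[4:6, 4:6] <- block_agc
  landscape(m)
}

# uniform landscape of one AGC value
flat_landscape <- function(agc = 100, nr = 7, nc = 7) {
  landscape(matrix(agc, nr, nc))
}

silvanus_traits <- function() {
  c(agc_optimum = 180, agc_tolerance = 90, dispersal_mean = 30,
    dispersal_shape = 10)
}

flavilateralis_traits <- function() {
  c(agc_optimum = 50, agc_tolerance = 47, dispersal_mean = 15,
    dispersal_shape = 5)
}

# a settled population of n homozygous birds of one species on one patch
founder_population <- function(n, species = "silvanus", row = 1L, col = 1L,
                               sex = NULL, weight = 1L, id0 = 1L) {
  traits <- if (species == "silvanus") silvanus_traits() else flavilateralis_traits()
  gn <- founder_genomes(n, traits, species)
  zosterosim:::birds_from_genomes(
    ids = id0:(id0 + n - 1L), species = species,
    sex = sex %||% rep_len(c("F", "M"), n),
    row = row, col = col, genomes = gn, age = 1L, weight = weight
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pair up birds i and j in a population tibble
link_pair <- function(pop, i, j) {
  pop$partner[i] <- pop$id[j]
  pop$partner[j] <- pop$id[i]
  pop$weight[c(i, j)] <- 1L
  pop
}

# an F1 hybrid genome set (one silvanus gamete, one flavilateralis gamete)
f1_genomes <- function(n = 1) {
  gs <- meiosis(founder_genomes(n, silvanus_traits(), "silvanus"))
  gf <- meiosis(founder_genomes(n, flavilateralis_traits(), "flavilateralis"))
  fuse(gs, gf)
}
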