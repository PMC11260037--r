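test_that("meiosis copies a parental strand when nothing can recombine", {
  set.seed(1)
  # zero map length: no crossover possible, mutation off
  parent <- cbind(c(0L, 1L, 0L, 1L), c(1L, 0L, 1L, 0L))
  g <- meiosis(parent, map = c(0, 0, 0, 0), mutation_rate = 0, length_cM = 0)
  expect_true(identical(g, parent[, 1]) || identical(g, parent[, 2]))

  # homozygous parent: gamete equals either (identical) strand
  hom <- cbind(c(1L, 0L, 1L), c(1L, 0L, 1L))
  g2 <- meiosis(hom, map = c(10, 50, 90), mutation_rate = 0, length_cM = 100)
  expect_identical(g2, hom[, 1])
})

test_that("recombination fraction at 10 cM matches the Haldane map function", {
  set.seed(2)
  n <- 1e5
  # heterozygous parent phased 0|1 at two loci 10 cM apart
  parent <- matrix(as.raw(c(0, 0, 1, 1)), nrow = 2)
  gam <- matesim:::cpp_gametes(parent, rep(1L, n), c(45, 55), 100, 0)
  recomb <- mean(gam[1, ] != gam[2, ])
  c_hald <- 0.5 * (1 - exp(-2 * 0.10))
  se <- sqrt(c_hald * (1 - c_hald) / n)
  expect_lt(abs(recomb - c_hald), 3 * se)
})

test_that("mutation flips alleles at the nominal rate", {
  set.seed(3)
  n <- 2e4
  L <- 50
  parent <- matrix(as.raw(0), L, 2) # homozygous 0 everywhere
  gam <- matesim:::cpp_gametes(parent, rep(1L, n), seq_len(L) * 2, 0, 1e-3)
  rate <- mean(as.integer(gam))
  se <- sqrt(1e-3 * (1 - 1e-3) / (n * L))
  expect_lt(abs(rate - 1e-3), 3 * se)
})

test_that("size schedule interpolates the census linearly and stays even", {
  s <- size_schedule(scale = 1)
  expect_equal(nrow(s), 2021)
  expect_equal(s$size[1], 1000)
  expect_equal(s$size[1001], 1000)
  expect_equal(s$size[2001], 10000)
  expect_equal(s$size[2021], 4000)
  expect_true(all(s$size %% 2 == 0))
  # growth phase is linear up to even-rounding: increments straddle 9000/1000
  expect_true(all(diff(s$size[1001:2001]) %in% c(8L, 10L)))
  expect_equal(s$size[2001] - s$size[1001], 9000L)
  s2 <- size_schedule(scale = 0.5)
  expect_equal(max(s2$generation), 1010)
  expect_equal(s2$size[1], 500)
  expect_equal(dplyr::last(s2$size), 2000)
})

test_that("zero-generation schedule returns the founder population", {
  set.seed(4)
  map <- build_genome_map(30, 5)
  pop <- simulate_historical(map, tibble::tibble(generation = 0L, size = 100L))
  expect_equal(n_individuals(pop), 100)
  expect_equal(pop$generation, 0L)
  expect_equal(sum(pop$sex == "M"), 50)
  p <- allele_freq(pop)
  expect_lt(abs(mean(p) - 0.5), 0.05)
})

test_that("census sizes are realized generation by generation", {
  set.seed(5)
  map <- build_genome_map(20, 2)
  sched <- tibble::tibble(generation = 0:10,
                          size = c(40L, 40L, 40L, 60L, 80L, 100L, 100L, 80L, 60L, 40L, 20L))
  pop <- simulate_historical(map, sched, keep_generations = 1:10)
  snaps <- attr(pop, "snapshots")
  got <- vapply(as.character(1:10), function(g) n_individuals(snaps[[g]]), 1L)
  expect_equal(unname(got), sched$size[-1])
})

test_that("heterozygosity decays like (1 - 1/2N)^t under pure drift", {
  set.seed(6)
  map <- build_genome_map(99, 1) # 100 loci
  sched <- tibble::tibble(generation = 0:100, size = 50L)
  het <- replicate(200, {
    pop <- simulate_historical(map, sched, mutation_rate = 0)
    p <- allele_freq(pop)
    mean(2 * p * (1 - p))
  })
  expected <- 0.5 * (1 - 1 / 100)^100
  se <- sd(het) / sqrt(length(het))
  expect_lt(abs(mean(het) - expected), 3 * se)
})

test_that("drift is directionless: mean allele frequency stays at 0.5", {
  set.seed(7)
  map <- build_genome_map(99, 1)
  sched <- tibble::tibble(generation = 0:60, size = 30L)
  pbar <- replicate(120, mean(allele_freq(simulate_historical(map, sched, mutation_rate = 0))))
  se <- sd(pbar) / sqrt(length(pbar))
  expect_lt(abs(mean(pbar) - 0.5), 3 * se)
})

test_that("segregating loci match hand counts on printed fixtures", {
  # 4 haplotypes (2 individuals) x 5 loci, written out explicitly
  h <- matrix(c(
    0, 1, 0, 1, # locus 1: segregating
    1, 1, 1, 1, # locus 2: fixed at 1
    0, 0, 0, 0, # locus 3: fixed at 0
    0, 0, 0, 1, # locus 4: segregating
    1, 0, 1, 0  # locus 5: segregating
  ), nrow = 5, byrow = TRUE)
  pop <- haplo_pop(h, sex = c("M", "F"))
  expect_equal(segregating_loci(pop), c(1L, 4L, 5L))
  all_het <- haplo_pop(matrix(c(0, 1, 0, 1, 0, 1), nrow = 3), sex = "F")
  expect_equal(segregating_loci(all_het), 1:3)
})

test_that("a bottleneck raises adjacent-marker LD", {
  set.seed(8)
  map <- build_genome_map(60, 2)
  pos <- map$pos_cM[marker_loci(map)]
  adj_r2 <- function(pop) {
    H <- matrix(as.integer(pop$haplo[marker_loci(map), ]), length(marker_loci(map)))
    pr <- matesim:::ld_pair_r2(H, pos, max_dist = 2.5)
    mean(pr$r2)
  }
  sched <- tibble::tibble(generation = 0:50,
                          size = c(rep(150L, 41), as.integer(seq(150, 30, length.out = 10))))
  diffs <- replicate(8, {
    pop <- simulate_historical(map, sched, keep_generations = 40L)
    pre <- attr(pop, "snapshots")[["40"]]
    adj_r2(pop) - adj_r2(pre)
  })
  expect_gt(mean(diffs), 0)
})

test_that("historical simulation is bit-reproducible for a fixed seed", {
  map0 <- withr::with_seed(9, build_genome_map(25, 5))
  sched <- tibble::tibble(generation = 0:20, size = 40L)
  p1 <- withr::with_seed(10, simulate_historical(map0, sched))
  p2 <- withr::with_seed(10, simulate_historical(map0, sched))
  expect_identical(p1$haplo, p2$haplo)
  expect_identical(p1$sex, p2$sex)
})
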