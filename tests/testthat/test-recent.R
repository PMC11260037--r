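make_expanded <- function(map, n = 160, seed = 30) {
  withr::with_seed(seed, {
    sched <- tibble::tibble(generation = 0:15, size = as.integer(n))
    hist <- simulate_historical(map, sched)
    haplo_pop(hist$haplo, sample(rep(c("M", "F"), length.out = n)),
              generation = hist$generation)
  })
}

test_that("expansion keeps zero generations as the founder draw and grows dams", {
  set.seed(31)
  map <- build_genome_map(40, 5)
  hist <- make_expanded(map)
  f0 <- expand_population(hist, map, n_sires = 10, n_dams = 40, n_gen = 0,
                          litter = 3)
  expect_equal(n_individuals(f0), 50)
  expect_equal(sum(f0$sex == "M"), 10)

  ex <- expand_population(hist, map, n_sires = 10, n_dams = 40, n_gen = 3,
                          litter = 4, max_dams = 1000)
  # dam quota doubles per generation (litter 4 -> 2 expected female offspring
  # per dam), capped by realized female availability
  n_dams_final <- n_individuals(ex) / 4
  expect_equal(ex$generation, 3L)
  expect_gte(n_dams_final, 40 * 2^2 * 0.7)
  expect_lte(n_dams_final, 40 * 2^2)

  expect_error(expand_population(hist, map, n_sires = 100, n_dams = 100),
               class = "matesim_sim_error")
})

test_that("the dam quota cap limits expansion growth", {
  set.seed(32)
  map <- build_genome_map(30, 3)
  hist <- make_expanded(map)
  ex <- expand_population(hist, map, n_sires = 10, n_dams = 40, n_gen = 4,
                          litter = 4, max_dams = 60)
  expect_equal(n_individuals(ex), 240) # 60 dams x litter 4
})

run_tiny_study <- function(design = "random", h2 = 0.6, n_gen = 10, seed = 33,
                           selection = "random", ...) {
  withr::with_seed(seed, {
    map <- build_genome_map(60, 8)
    hist <- make_expanded(map, n = 200, seed = seed + 1)
    ex <- expand_population(hist, map, n_sires = 15, n_dams = 60, n_gen = 2,
                            litter = 4, max_dams = 120)
    eff <- sample_qtl_effects(8)
    simulate_recent(ex, map, design, eff, h2, n_sires = 6, n_dams = 30,
                    n_gen = n_gen, litter = 4, selection = selection, ...)
  })
}

test_that("reference and validation masks partition generations 3 through 10", {
  st <- run_tiny_study()
  a <- st$animals
  expect_setequal(unique(a$generation[!is.na(a$set) & a$set == "reference"]), 3:9)
  expect_setequal(unique(a$generation[!is.na(a$set) & a$set == "validation"]), 10)
  expect_equal(sum(!is.na(a$set)), sum(a$generation >= 3))
  expect_equal(nrow(a[a$generation == 10, ]), 30 * 4)
  # every animal appears once; parents precede offspring
  expect_equal(anyDuplicated(a$id), 0)
  ord <- match(a$sire, a$id)
  expect_true(all(is.na(ord) | ord < seq_len(nrow(a))))
  # genotypes stored for every reference/validation generation
  expect_setequal(names(st$genotypes), as.character(3:10))
  expect_equal(nrow(st$genotypes[["5"]]), sum(a$generation == 5))
})

test_that("recorded inbreeding equals tabular kinship of the parents", {
  st <- run_tiny_study(n_gen = 4)
  a <- st$animals
  K <- kinship_matrix(a[, c("id", "sire", "dam")])
  off <- a[!is.na(a$sire), ]
  expect_equal(off$f,
               K[cbind(as.character(off$sire), as.character(off$dam))],
               tolerance = 1e-12)
})

test_that("realized heritability in early generations matches the target", {
  set.seed(34)
  ratios <- vapply(1:8, function(i) {
    st <- run_tiny_study(h2 = 0.6, n_gen = 2, seed = 100 + i)
    g1 <- st$animals[st$animals$generation == 1, ]
    var(g1$tbv) / var(g1$phenotype)
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.6), 3 * se + 0.02)
})

test_that("invalid designs and shortfalls raise classed errors", {
  expect_error(run_tiny_study(design = "fancy"), class = "matesim_config_error")
  set.seed(35)
  map <- build_genome_map(20, 3)
  hist <- make_expanded(map, n = 100, seed = 36)
  ex <- expand_population(hist, map, n_sires = 5, n_dams = 20, n_gen = 1,
                          litter = 4, max_dams = 40)
  eff <- sample_qtl_effects(3)
  # litter 1 cannot replace 20 dams from ~10 female offspring
  expect_error(
    simulate_recent(ex, map, "random", eff, 0.3, n_sires = 2, n_dams = 20,
                    n_gen = 3, litter = 1),
    class = "matesim_sim_error")
})

test_that("positive assortative mating inflates progeny TBV variance vs random", {
  set.seed(37)
  diffs <- vapply(1:20, function(i) {
    cfg_a <- tiny_cfg(design = "assortative_pos", h2 = 0.6, master_seed = 500)
    cfg_r <- tiny_cfg(design = "random", h2 = 0.6, master_seed = 500)
    h <- shared_history(cfg_a, derive_seed(500, i, "history"))
    va <- run_replicate(cfg_a, i, history = h)$var_tbv_val
    vr <- run_replicate(cfg_r, i, history = h)$var_tbv_val
    va - vr
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs) / (sd(diffs) / sqrt(length(diffs))), 1.7) # one-sided
})

test_that("EBV-truncation selection is available and raises the mean TBV", {
  st_r <- run_tiny_study(selection = "random", seed = 38)
  st_s <- run_tiny_study(selection = "ebv", seed = 38)
  mean_val <- function(st) mean(st$animals$tbv[st$animals$generation == 10])
  expect_gt(mean_val(st_s), mean_val(st_r))
})
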