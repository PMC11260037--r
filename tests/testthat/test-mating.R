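test_that("tabular kinship reproduces textbook identities", {
  two <- data.frame(id = 1:2, sire = NA, dam = NA)
  K <- kinship_matrix(two)
  expect_equal(unname(diag(K)), c(0.5, 0.5))
  expect_equal(K[1, 2], 0)

  # full sibs from unrelated parents: kinship 1/4; their offspring F = 1/4
  ped <- data.frame(id = 1:5, sire = c(NA, NA, 1, 1, 3), dam = c(NA, NA, 2, 2, 4))
  K <- kinship_matrix(ped)
  expect_equal(K["3", "4"], 0.25)
  expect_equal(unname(inbreeding_from_kinship(K)["5"]), 0.25)

  expect_error(kinship_matrix(data.frame(id = 1:2, sire = c(2, NA), dam = NA)),
               class = "matesim_pedigree_error")
})

test_that("kinship matrix equals the path-counting oracle on a 6-animal pedigree", {
  # half-sib and inbred structure: 5 = (3 x 4) with 3,4 sharing sire 1
  ped <- data.frame(id = 1:6,
                    sire = c(NA, NA, 1, 1, 3, 3),
                    dam = c(NA, NA, 2, 2, 4, 4))
  expect_equal(kinship_matrix(ped), kinship_oracle(ped), tolerance = 1e-12)
})

test_that("random pairing covers every dam with near-equal sire usage", {
  set.seed(20)
  plan <- pair_random(1, letters[1:5])
  expect_equal(sort(plan$dam), letters[1:5])
  expect_true(all(plan$sire == 1))

  sires <- paste0("s", 1:50)
  dams <- paste0("d", 1:3500)
  plan <- pair_random(sires, dams)
  expect_equal(as.integer(table(plan$sire)), rep(70L, 50))
  expect_equal(sort(plan$dam), sort(dams))
  expect_silent(validate_mate_plan(plan, sires, dams))

  plan7 <- pair_random(paste0("s", 1:3), paste0("d", 1:7))
  expect_lte(diff(range(table(plan7$sire))), 1)
})

test_that("assortative pairing matches and anti-matches EBV ranks", {
  ebv <- c(s1 = 1.0, s2 = 0.0, d1 = 0.9, d2 = -0.2)
  pos <- pair_assortative(c("s1", "s2"), c("d1", "d2"), ebv, "positive")
  expect_equal(pos$dam[pos$sire == "s1"], "d1")
  expect_equal(pos$dam[pos$sire == "s2"], "d2")
  neg <- pair_assortative(c("s1", "s2"), c("d1", "d2"), ebv, "negative")
  expect_equal(neg$dam[neg$sire == "s1"], "d2")
  expect_equal(neg$dam[neg$sire == "s2"], "d1")
  expect_error(pair_assortative(c("s1", "sX"), c("d1", "d2"), ebv, "positive"),
               class = "matesim_config_error")
})

test_that("assortative block allocation is rank-optimal among balanced plans", {
  set.seed(21)
  sires <- paste0("s", 1:3)
  dams <- paste0("d", 1:6)
  ebv <- setNames(c(rnorm(3), rnorm(6)), c(sires, dams))
  rank_s <- setNames(rank(ebv[sires]), sires)
  rank_d <- setNames(rank(ebv[dams]), dams)
  score <- function(assign) sum(rank_s[sires[assign]] * rank_d[dams])
  all_scores <- apply(balanced_allocations(3, 6), 1, score)
  plan_p <- pair_assortative(sires, dams, ebv, "positive")
  assign_p <- match(plan_p$sire[match(dams, plan_p$dam)], sires)
  expect_equal(score(assign_p), max(all_scores))
  plan_n <- pair_assortative(sires, dams, ebv, "negative")
  assign_n <- match(plan_n$sire[match(dams, plan_n$dam)], sires)
  expect_equal(score(assign_n), min(all_scores))
})

sa_toy_kinship <- function() {
  ids <- c(paste0("s", 1:3), paste0("d", 1:3))
  K <- matrix(0.05, 6, 6, dimnames = list(ids, ids))
  diag(K) <- 0.5
  K["s1", "d1"] <- K["d1", "s1"] <- 0.30
  K["s1", "d2"] <- K["d2", "s1"] <- 0.02
  K["s2", "d2"] <- K["d2", "s2"] <- 0.25
  K["s2", "d3"] <- K["d3", "s2"] <- 0.01
  K["s3", "d3"] <- K["d3", "s3"] <- 0.40
  K["s3", "d1"] <- K["d1", "s3"] <- 0.03
  K
}

test_that("simulated annealing attains the enumerated optimum on 3x3 plans", {
  K <- sa_toy_kinship()
  sires <- paste0("s", 1:3)
  dams <- paste0("d", 1:3)
  allocs <- balanced_allocations(3, 3)
  objs <- apply(allocs, 1, function(a) mean(K[cbind(sires[a], dams)]))
  set.seed(22)
  for (obj in c("min", "max")) {
    target <- if (obj == "min") min(objs) else max(objs)
    got <- replicate(100, attr(pair_inbreeding_opt(sires, dams, K, obj), "objective"))
    expect_equal(got, rep(target, 100), tolerance = 1e-12)
  }
})

test_that("annealing degenerate and bound cases behave", {
  ids <- c("s1", "s2", "d1", "d2")
  K0 <- matrix(0, 4, 4, dimnames = list(ids, ids)); diag(K0) <- 0.5
  set.seed(23)
  plan <- pair_inbreeding_opt(c("s1", "s2"), c("d1", "d2"), K0, "min")
  expect_equal(attr(plan, "objective"), 0)

  # sires are full sibs of the dams: every pairing has kinship 1/4, so the
  # maximised mean expected progeny inbreeding hits the full-sib bound
  ped <- data.frame(id = 1:6, sire = c(NA, NA, 1, 1, 1, 1),
                    dam = c(NA, NA, 2, 2, 2, 2))
  Kfs <- kinship_matrix(ped)
  planfs <- pair_inbreeding_opt(c("3", "4"), c("5", "6"), Kfs, "max")
  expect_equal(attr(planfs, "objective"), 0.25)
  expect_equal(planfs$exp_progeny_f, c(0.25, 0.25))

  expect_error(pair_inbreeding_opt(character(0), c("d1"), K0, "min"),
               class = "matesim_config_error")
})

test_that("best-so-far annealing objective is monotone within a run", {
  K <- sa_toy_kinship()
  set.seed(24)
  plan <- pair_inbreeding_opt(paste0("s", 1:3), paste0("d", 1:3), K, "min",
                              trace = TRUE)
  tr <- attr(plan, "trace")
  expect_false(is.null(tr))
  expect_true(all(diff(tr$best) <= 1e-15))
  expect_true(all(diff(tr$temperature) < 0))
})

test_that("mean expected progeny inbreeding orders min <= random <= max", {
  # related candidates: two full-sib families plus a cousin family
  ped <- data.frame(id = 1:14,
                    sire = c(NA, NA, NA, NA, 1, 1, 1, 3, 3, 3, 1, 3, 1, 3),
                    dam = c(NA, NA, NA, NA, 2, 2, 2, 4, 4, 4, 4, 2, 2, 4))
  K <- kinship_matrix(ped)
  sires <- as.character(5:8)
  dams <- as.character(9:14)
  set.seed(25)
  res <- t(replicate(20, {
    c(min = attr(pair_inbreeding_opt(sires, dams, K, "min"), "objective"),
      rnd = mean(pair_random(sires, dams, K)$exp_progeny_f),
      max = attr(pair_inbreeding_opt(sires, dams, K, "max"), "objective"))
  }))
  expect_lt(mean(res[, "min"]), mean(res[, "rnd"]))
  expect_lt(mean(res[, "rnd"]), mean(res[, "max"]))
})

test_that("mate plans can be written out", {
  set.seed(26)
  plan <- pair_random(1:2, 1:6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mate_plan(plan, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 6)
  expect_named(back, c("sire", "dam", "exp_progeny_f"))
})
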