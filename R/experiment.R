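#' Scenario configuration
#'
#' Bundles every knob of one simulation scenario: genetic architecture
#' (marker density, QTL number, heritability), mating design, replicate
#' count, and the demographic preset. The paper-scale preset (scale = 1) is
#' the full schedule: 1000-founder historical population grown to 10,000 and
#' bottlenecked to 4,000 over 2020 generations, a 500-sire x 3,500-dam
#' expansion (10 generations, litter 5), and a 50-sire x 3,500-dam recent
#' population (10 generations) whose generations 3-9 are the reference set
#' and generation 10 the validation set. `scale` shrinks all census sizes
#' and historical phase lengths proportionally (see [size_schedule()]);
#' the recent/expansion generation structure is part of the design and is
#' never scaled.
#'
#' @param n_markers Marker count (paper grid: 350, 650, 950).
#' @param n_qtl QTL count (paper grid: 50, 150, 200).
#' @param h2 Heritability (paper grid: 0.05, 0.30, 0.60).
#' @param design Mating design tag (see [simulate_recent()]).
#' @param n_replicates Replicates per scenario (paper: 20).
#' @param scale Proportional shrink factor for all census sizes and
#'   historical phase lengths.
#' @param master_seed Master seed; replicate and stage seeds are derived
#'   deterministically from it.
#' @param litter Offspring per dam in the expansion and recent phases.
#' @param sigma_p2 Phenotypic variance.
#' @param mutation_rate Per-locus per-generation allele-flip rate.
#' @param length_cM Chromosome length.
#' @param n_gen_expansion,n_gen_recent Generation counts of the two phases.
#' @param exp_sires,exp_dams,exp_max_dams,n_sires,n_dams Optional explicit
#'   overrides of the scaled census counts (defaults: paper values times
#'   `scale`).
#' @param selection Next-generation parent choice in the recent phase
#'   (`"random"` or `"ebv"`), see [simulate_recent()].
#' @param sa_control Simulated-annealing overrides for the inbreeding
#'   designs.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_markers = 950, n_qtl = 50, h2 = 0.30,
                            design = "random", n_replicates = 20, scale = 1,
                            master_seed = 1, litter = 5, sigma_p2 = 1,
                            mutation_rate = 2.5e-5, length_cM = 100,
                            n_gen_expansion = 10, n_gen_recent = 10,
                            exp_sires = NULL, exp_dams = NULL,
                            exp_max_dams = NULL, n_sires = NULL,
                            n_dams = NULL, selection = "random",
                            sa_control = list()) {
  sc <- function(x, base, lo = 2L) if (!is.null(x)) as.integer(x) else
    max(lo, as.integer(round(base * scale)))
  cfg <- list(
    n_markers = as.integer(n_markers), n_qtl = as.integer(n_qtl), h2 = h2,
    design = design, n_replicates = as.integer(n_replicates), scale = scale,
    master_seed = as.integer(master_seed), litter = litter,
    sigma_p2 = sigma_p2, mutation_rate = mutation_rate,
    length_cM = length_cM, n_gen_expansion = as.integer(n_gen_expansion),
    n_gen_recent = as.integer(n_gen_recent),
    exp_sires = sc(exp_sires, 500), exp_dams = sc(exp_dams, 3500),
    exp_max_dams = sc(exp_max_dams, 10000),
    n_sires = sc(n_sires, 50), n_dams = sc(n_dams, 3500),
    selection = selection, sa_control = sa_control
  )
  if (cfg$n_markers < 2 || cfg$n_qtl < 1 || cfg$h2 < 0 || cfg$h2 > 1 ||
      cfg$n_replicates < 1 || cfg$scale <= 0 || cfg$litter < 1)
    abort("Invalid scenario configuration.", class = "matesim_config_error")
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s | %d markers, %d QTL, h2 = %g | scale %g, %d replicates, seed %d\n",
              x$design, x$n_markers, x$n_qtl, x$h2, x$scale, x$n_replicates,
              x$master_seed))
  invisible(x)
}

scenario_id <- function(cfg) {
  paste(cfg$design, cfg$n_markers, cfg$n_qtl, cfg$h2, sep = "_")
}

#' Derive a child seed deterministically
#'
#' Folds a master seed and any number of numeric or character tags into a
#' new seed in `[1, 2^31 - 1)`, so every replicate and pipeline stage draws
#' from its own reproducible stream.
#'
#' @param master Master seed.
#' @param ... Numeric or character tags (replicate index, stage name, ...).
#' @return Integer seed.
#' @export
derive_seed <- function(master, ...) {
  parts <- c(list(master), list(...))
  acc <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
         else as.numeric(p)
    acc <- (acc * 69069 + v * 12345 + 1) %% 2147483563
  }
  as.integer(acc) + 1L
}

#' Simulate the scenario-independent history of one replicate
#'
#' Builds the union genome map (the densest marker grid plus the largest
#' QTL-candidate set of the scenarios that will share it) and runs the
#' historical and expansion phases, which involve no selection and no trait,
#' so they can be shared across scenarios of one replicate index. Scenarios
#' then pick their marker subset nearest to the equally spaced target grid
#' and sample their QTL from the candidates.
#'
#' @param cfg A `scenario_config` providing the demographic preset.
#' @param seed Seed for this history.
#' @param n_markers,n_qtl Union dimensions (defaults: the config's own).
#' @return A `sim_history` list: `map`, `expanded`, `seed`, dimensions.
#' @export
shared_history <- function(cfg, seed, n_markers = cfg$n_markers,
                           n_qtl = cfg$n_qtl) {
  set.seed(seed)
  map <- build_genome_map(n_markers, n_qtl, cfg$length_cM)
  sched <- size_schedule(cfg$scale)
  hist <- simulate_historical(map, sched, cfg$mutation_rate)
  expanded <- expand_population(
    hist, map, n_sires = cfg$exp_sires, n_dams = cfg$exp_dams,
    n_gen = cfg$n_gen_expansion, litter = cfg$litter,
    max_dams = cfg$exp_max_dams, mutation_rate = cfg$mutation_rate)
  structure(list(map = map, expanded = expanded, seed = seed,
                 n_markers = n_markers, n_qtl = n_qtl),
            class = "sim_history")
}

# Scenario markers: nearest union-grid marker to each equally spaced target
# position. Exact when the counts match.
select_marker_rows <- function(map, n_markers) {
  mrows <- which(map$role == "marker")
  m_all <- length(mrows)
  if (n_markers > m_all)
    abort("Scenario requests more markers than the union map carries.",
          class = "matesim_config_error")
  if (n_markers == m_all) return(mrows)
  sel <- pmin(m_all, pmax(1L, as.integer(round(seq_len(n_markers) * m_all / n_markers))))
  if (anyDuplicated(sel))
    abort("Marker down-sampling produced duplicates.", class = "matesim_config_error")
  mrows[sel]
}

#' Run one scenario replicate end-to-end
#'
#' Executes the full pipeline for one replicate: historical simulation and
#' expansion (or a supplied shared history), QTL sampling and effect
#' scaling, the recent population under the scenario's mating design, an
#' RR-BLUP fit on the pooled reference generations, GEBV for reference and
#' validation animals, and the accuracy/bias (and optionally LD) metrics.
#' Fully deterministic given `(cfg, replicate, history)`.
#'
#' @param cfg A `scenario_config`.
#' @param replicate Replicate index (seeds are derived from
#'   `cfg$master_seed` and this index).
#' @param history Optional `sim_history` to reuse across scenarios.
#' @param ld If `TRUE`, store reference haplotypes and attach the binned LD
#'   table (list column `ld`) and pooled mean r2 (`mean_r2`).
#' @return One-row tibble: scenario descriptors, `replicate`, `a_ref`,
#'   `a_val` (reference/validation accuracy), `bias` and `bias_se` (pooled
#'   TBV-on-GEBV slope), `n_ref`, `n_val`, `var_tbv_val`, `mean_f_val`, and
#'   LD columns when requested.
#' @export
run_replicate <- function(cfg, replicate = 1L, history = NULL, ld = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  rep_seed <- derive_seed(cfg$master_seed, replicate)
  if (is.null(history))
    history <- shared_history(cfg, derive_seed(rep_seed, "history"))
  set.seed(derive_seed(rep_seed, scenario_id(cfg)))
  marker_idx <- select_marker_rows(history$map, cfg$n_markers)
  qtl_all <- which(history$map$role == "qtl")
  if (cfg$n_qtl > length(qtl_all))
    abort("Scenario requests more QTL than the union map carries.",
          class = "matesim_config_error")
  qtl_idx <- sort(sample(qtl_all, cfg$n_qtl))
  effects <- sample_qtl_effects(cfg$n_qtl)
  study <- simulate_recent(
    history$expanded, history$map, cfg$design, effects, cfg$h2,
    sigma_p2 = cfg$sigma_p2, n_sires = cfg$n_sires, n_dams = cfg$n_dams,
    n_gen = cfg$n_gen_recent, litter = cfg$litter,
    mutation_rate = cfg$mutation_rate, marker_idx = marker_idx,
    qtl_idx = qtl_idx, selection = cfg$selection,
    store_haplotypes = ld, sa_control = cfg$sa_control)
  pred <- predict_study(study)
  a <- study_accuracy(study, pred)
  row <- tibble::tibble(
    design = cfg$design, n_markers = cfg$n_markers, n_qtl = cfg$n_qtl,
    h2 = cfg$h2, replicate = as.integer(replicate), seed = rep_seed,
    a_ref = a$a_ref, a_val = a$a_val, bias = a$bias, bias_se = a$bias_se,
    n_ref = a$n_ref, n_val = a$n_val,
    var_tbv_val = a$var_tbv_val, mean_f_val = a$mean_f_val)
  if (ld) {
    row$mean_r2 <- ld_mean_r2(study)
    row$ld <- list(ld_decay(study))
  }
  row
}

#' Fit RR-BLUP on the reference set and predict all genotyped animals
#'
#' Pools the reference generations into one SNP-BLUP fit (segregating
#' markers only; ridge factor from [default_lambda()] with the reference
#' allele frequencies) and computes `GEBV = X g_hat` for reference and
#' validation animals.
#'
#' @param study A `study_pop`.
#' @param lambda Optional user ridge factor overriding [default_lambda()].
#' @return List with the `fit` and a `scores` tibble (`id`, `generation`,
#'   `set`, `tbv`, `gebv`).
#' @export
predict_study <- function(study, lambda = NULL) {
  ref_gens <- as.character(study$reference_generations)
  val_gen <- as.character(study$n_gen)
  a <- study$animals
  ref <- a[!is.na(a$set) & a$set == "reference", ]
  val <- a[!is.na(a$set) & a$set == "validation", ]
  m <- length(study$marker_idx)
  # accumulate the mixed-model blocks generation by generation so the pooled
  # reference dosage matrix is never materialised (memory, not speed)
  XtX <- matrix(0, m, m)
  Xty <- numeric(m)
  csum <- numeric(m)
  cmin <- rep(Inf, m)
  cmax <- rep(-Inf, m)
  n <- 0L
  sum_y <- 0
  for (g in ref_gens) {
    Xg <- study$genotypes[[g]]
    yg <- ref$phenotype[ref$generation == as.integer(g)]
    stopifnot(nrow(Xg) == length(yg))
    storage.mode(Xg) <- "double"
    XtX <- XtX + crossprod(Xg)
    Xty <- Xty + drop(crossprod(Xg, yg))
    csum <- csum + colSums(Xg)
    cmin <- pmin(cmin, apply(Xg, 2, min))
    cmax <- pmax(cmax, apply(Xg, 2, max))
    n <- n + nrow(Xg)
    sum_y <- sum_y + sum(yg)
  }
  p <- csum / (2 * n)
  seg <- which(p > 0 & p < 1 & cmax > cmin)
  if (!length(seg))
    abort("No segregating markers in the reference set.",
          class = "matesim_config_error")
  comp <- if (is.null(lambda)) default_lambda(study$trait$h2, study$trait$sigma_p2, p[seg])
          else list(sigma_g2 = NA_real_, lambda = lambda)
  sol <- rrblup_solve(XtX[seg, seg, drop = FALSE], Xty[seg], csum[seg],
                      n, sum_y, comp$lambda)
  fit <- structure(
    list(mu = sol$mu,
         effects = setNames(sol$effects, study$map$id[study$marker_idx][seg]),
         lambda = comp$lambda, kept = seq_along(seg), n = n, m = length(seg)),
    class = "rrblup_fit")
  score_gen <- function(g) {
    Xg <- study$genotypes[[g]][, seg, drop = FALSE]
    storage.mode(Xg) <- "double"
    drop(Xg %*% sol$effects)
  }
  gebv_ref <- unlist(lapply(ref_gens, score_gen), use.names = FALSE)
  scores <- tibble::tibble(
    id = c(ref$id, val$id),
    generation = c(ref$generation, val$generation),
    set = c(ref$set, val$set),
    tbv = c(ref$tbv, val$tbv),
    gebv = c(gebv_ref, score_gen(val_gen)))
  list(fit = fit, scores = scores)
}

#' Accuracy and bias of one study's prediction
#'
#' Reference accuracy A_T, validation accuracy A_V (Pearson correlations of
#' TBV with GEBV) and the pooled TBV-on-GEBV regression slope.
#'
#' @param study A `study_pop`.
#' @param pred Result of [predict_study()] (computed if missing).
#' @return One-row tibble: `a_ref`, `a_val`, `bias`, `bias_se`, `n_ref`,
#'   `n_val`, `var_tbv_val`, `mean_f_val`.
#' @export
study_accuracy <- function(study, pred = predict_study(study)) {
  s <- pred$scores
  ref <- s[s$set == "reference", ]
  val <- s[s$set == "validation", ]
  b <- bias_slope(s$tbv, s$gebv)
  tibble::tibble(
    a_ref = accuracy(ref$tbv, ref$gebv),
    a_val = accuracy(val$tbv, val$gebv),
    bias = b$slope, bias_se = b$se,
    n_ref = nrow(ref), n_val = nrow(val),
    var_tbv_val = var(val$tbv),
    mean_f_val = mean(study$animals$f[study$animals$generation == study$n_gen]))
}

#' Run a grid of scenarios with shared replicate histories
#'
#' Runs every scenario for every replicate index. With `share_history =
#' TRUE` (default) all scenarios of one replicate index reuse one
#' historical+expansion simulation built on the union map (densest marker
#' grid, largest QTL-candidate set), so marker-density and design
#' comparisons see the same genetic background. Failures in single runs are
#' recorded and the grid continues.
#'
#' @param cfgs A `scenario_config` or list of them. For sharing, all
#'   configs must agree on the demographic preset and master seed.
#' @param ld Compute LD tables per replicate (costly).
#' @param share_history Share one history per replicate index.
#' @param progress Print one line per completed run.
#' @return A `scenario_results` object: list with `replicates` (one row per
#'   run, including an `error` column) and `summary` (per-scenario mean and
#'   SE over replicates).
#' @export
run_grid <- function(cfgs, ld = FALSE, share_history = TRUE, progress = FALSE) {
  if (inherits(cfgs, "scenario_config")) cfgs <- list(cfgs)
  stopifnot(length(cfgs) >= 1, all(purrr::map_lgl(cfgs, inherits, "scenario_config")))
  base <- cfgs[[1]]
  if (share_history && length(cfgs) > 1) {
    same <- purrr::map_lgl(cfgs, function(cc) {
      all(purrr::map_lgl(c("scale", "master_seed", "litter", "length_cM",
                           "mutation_rate", "n_gen_expansion", "n_gen_recent",
                           "exp_sires", "exp_dams", "exp_max_dams",
                           "n_sires", "n_dams"),
                         function(f) identical(cc[[f]], base[[f]])))
    })
    if (!all(same))
      abort("Shared histories need identical demographic presets and master seed.",
            class = "matesim_config_error")
  }
  n_markers_max <- max(purrr::map_int(cfgs, "n_markers"))
  n_qtl_max <- max(purrr::map_int(cfgs, "n_qtl"))
  r_max <- max(purrr::map_int(cfgs, "n_replicates"))
  rows <- list()
  for (r in seq_len(r_max)) {
    history <- NULL
    if (share_history) {
      hseed <- derive_seed(derive_seed(base$master_seed, r), "history")
      history <- shared_history(base, hseed, n_markers_max, n_qtl_max)
    }
    for (cfg in cfgs) {
      if (cfg$n_replicates < r) next
      res <- tryCatch(
        dplyr::mutate(run_replicate(cfg, r, history = history, ld = ld),
                      error = NA_character_),
        error = function(e) tibble::tibble(
          design = cfg$design, n_markers = cfg$n_markers, n_qtl = cfg$n_qtl,
          h2 = cfg$h2, replicate = as.integer(r), error = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- res
      if (progress)
        message(sprintf("replicate %d | %s: a_val = %s", r, scenario_id(cfg),
                        if (!is.null(res$a_val)) sprintf("%.3f", res$a_val) else "failed"))
      gc(FALSE)
    }
  }
  replicates <- dplyr::bind_rows(rows)
  structure(list(replicates = replicates,
                 summary = summarize_results(replicates)),
            class = "scenario_results")
}

#' Summarise replicate rows per scenario
#'
#' Mean and standard error over replicates of the reference accuracy,
#' validation accuracy and bias slope, one row per scenario.
#'
#' @param replicates Replicate tibble as produced by [run_replicate()] /
#'   [run_grid()].
#' @return Summary tibble.
#' @export
summarize_results <- function(replicates) {
  ok <- replicates
  if ("error" %in% names(ok)) ok <- ok[is.na(ok$error), ]
  dplyr::summarise(
    dplyr::group_by(ok, .data$design, .data$n_markers, .data$n_qtl, .data$h2),
    n_replicates = dplyr::n(),
    dplyr::across(dplyr::all_of(c("a_ref", "a_val", "bias")),
                  list(mean = mean, se = ~ if (dplyr::n() > 1) sd(.x) / sqrt(dplyr::n()) else 0)),
    .groups = "drop")
}

#' @export
print.scenario_results <- function(x, ...) {
  cat(sprintf("<scenario_results> %d replicate runs, %d scenario summaries\n",
              nrow(x$replicates), nrow(x$summary)))
  print(x$summary)
  invisible(x)
}

#' Build the scenario grid
#'
#' Expands marker density x QTL number x heritability x design into a list
#' of [scenario_config()]s sharing one demographic preset.
#'
#' @param n_markers,n_qtl,h2,designs Grid axes.
#' @param ... Passed to [scenario_config()] (preset, replicates, seed, ...).
#' @return List of `scenario_config`s.
#' @export
scenario_grid <- function(n_markers = c(350, 650, 950),
                          n_qtl = c(50, 150, 200),
                          h2 = c(0.05, 0.30, 0.60),
                          designs = c("random", "assortative_pos",
                                      "assortative_neg", "min_inbreeding",
                                      "max_inbreeding"), ...) {
  g <- tidyr::expand_grid(design = designs, n_markers = n_markers,
                          n_qtl = n_qtl, h2 = h2)
  purrr::pmap(g, function(design, n_markers, n_qtl, h2)
    scenario_config(n_markers = n_markers, n_qtl = n_qtl, h2 = h2,
                    design = design, ...))
}

#' Write grid results as CSV files
#'
#' `replicates.csv` (per-run rows, list columns dropped) and `summary.csv`
#' (per-scenario mean and SE) under `dir`.
#'
#' @param results A `scenario_results`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reps <- results$replicates
  reps <- reps[, !purrr::map_lgl(reps, is.list), drop = FALSE]
  utils::write.csv(as.data.frame(reps), file.path(dir, "replicates.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(results$summary),
                   file.path(dir, "summary.csv"), row.names = FALSE)
  invisible(dir)
}
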