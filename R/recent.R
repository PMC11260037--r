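#' Expand a historical population
#'
#' The expansion phase between the historical bottleneck and the recent
#' breeding population: founder sires and dams are drawn at random (without
#' replacement) from the final historical generation, then mated for `n_gen`
#' generations with `litter` offspring per dam and random sire allocation.
#' The dam quota grows geometrically (factor `litter / 2`, the expected
#' number of female offspring per dam) up to `max_dams`; sires are redrawn
#' from male offspring keeping the initial sire:dam ratio. Offspring sex is
#' Bernoulli(1/2).
#'
#' Historical sex labels are ignored when drawing founders: under random
#' union of gametes sex carries no genetic information, and the bottleneck
#' generation is smaller than the required number of dams.
#'
#' @param hist A `haplo_pop`, the final historical generation.
#' @param map The `genome_map` the haplotypes follow.
#' @param n_sires,n_dams Founder counts (paper scale 500 and 3500).
#' @param n_gen Expansion generations.
#' @param litter Offspring per dam.
#' @param max_dams Cap on the dam quota.
#' @param mutation_rate Per-locus per-generation allele-flip rate.
#' @return The final expanded-generation `haplo_pop`.
#' @export
expand_population <- function(hist, map, n_sires = 500, n_dams = 3500,
                              n_gen = 10, litter = 5, max_dams = 10000,
                              mutation_rate = 2.5e-5) {
  n_avail <- n_individuals(hist)
  if (n_avail < n_sires + n_dams)
    abort("Historical population too small for the requested founders.",
          class = "matesim_sim_error")
  pos <- map$pos_cM
  len <- map_length(map)
  founders <- sample.int(n_avail, n_sires + n_dams)
  cols <- as.vector(rbind(2L * founders - 1L, 2L * founders))
  pop <- haplo_pop(hist$haplo[, cols, drop = FALSE],
                   rep(c("M", "F"), c(n_sires, n_dams)),
                   generation = 0L)
  if (n_gen == 0) return(pop)
  ratio <- n_dams / n_sires
  quota <- n_dams
  for (g in seq_len(n_gen)) {
    sires <- which(pop$sex == "M")
    dams <- which(pop$sex == "F")
    plan_sire <- rep(sires, balanced_counts(length(dams), length(sires)))[sample.int(length(dams))]
    sire_idx <- rep(plan_sire, each = litter)
    dam_idx <- rep(dams, each = litter)
    child <- drop_offspring(pop$haplo, sire_idx, dam_idx, pos, len, mutation_rate)
    n_off <- length(dam_idx)
    sex <- ifelse(runif(n_off) < 0.5, "M", "F")
    pop <- haplo_pop(child, sex, generation = g)
    if (g < n_gen) {
      quota <- min(quota * litter / 2, max_dams)
      f_idx <- which(sex == "F")
      m_idx <- which(sex == "M")
      n_d <- min(length(f_idx), as.integer(round(quota)))
      n_s <- max(1L, min(length(m_idx), as.integer(round(n_d / ratio))))
      if (n_d < 1 || n_s < 1)
        abort("Offspring shortfall during expansion.", class = "matesim_sim_error")
      keep <- c(sample(m_idx, n_s), sample(f_idx, n_d))
      cols <- as.vector(rbind(2L * keep - 1L, 2L * keep))
      pop <- haplo_pop(pop$haplo[, cols, drop = FALSE],
                       rep(c("M", "F"), c(n_s, n_d)), generation = g)
    }
  }
  pop
}

# Kinship among selected offspring from parental kinship:
# k(o, o') = (k(s,s') + k(s,d') + k(d,s') + k(d,d')) / 4 off-diagonal,
# k(o, o) = (1 + k(s, d)) / 2 (the tabular-method recursion).
propagate_kinship <- function(K, si, di, ids) {
  # sequential accumulation keeps at most one n^2 temporary alive
  Kn <- K[si, si, drop = FALSE]
  Kn <- Kn + K[si, di, drop = FALSE]
  Kn <- Kn + K[di, si, drop = FALSE]
  Kn <- Kn + K[di, di, drop = FALSE]
  Kn <- Kn * 0.25
  diag(Kn) <- 0.5 * (1 + K[cbind(si, di)])
  dimnames(Kn) <- list(ids, ids)
  Kn
}

#' Simulate the recent breeding population under a mating design
#'
#' Runs the 10-generation recent phase: `n_sires` males and `n_dams` females
#' are drawn from the expanded population (generation 0), QTL effects are
#' scaled on that founder cohort so the trait heritability holds where
#' phenotypes are recorded, and each generation is produced by (1) computing
#' parent EBVs when the design needs them, (2) allocating mates under the
#' design, (3) dropping `litter` offspring per dam with recombination and
#' mutation, (4) assigning true breeding values and phenotypes, and
#' (5) drawing next-generation parents from the offspring. Generations
#' `reference_generations` form the training set (genotyped and phenotyped);
#' generation `n_gen` is the validation set (genotypes only enter
#' prediction).
#'
#' Pedigree kinship is propagated generation-to-generation, so every
#' animal's inbreeding coefficient (its parents' kinship) is recorded and
#' the inbreeding-optimising designs always see current kinship.
#'
#' @param expanded A `haplo_pop`, the final expanded generation.
#' @param map The full `genome_map` of the simulated haplotypes.
#' @param design One of `"random"`, `"assortative_pos"`, `"assortative_neg"`,
#'   `"min_inbreeding"`, `"max_inbreeding"`.
#' @param raw_effects Unscaled QTL effects, one per entry of `qtl_idx`.
#' @param h2 Narrow-sense heritability of the simulated trait.
#' @param sigma_p2 Phenotypic variance.
#' @param n_sires,n_dams Parents per generation (paper scale 50 and 3500).
#' @param n_gen Number of generations (validation generation).
#' @param litter Offspring per dam.
#' @param mutation_rate Per-locus per-generation allele-flip rate.
#' @param marker_idx Map row indices of the scenario's markers.
#' @param qtl_idx Map row indices of the scenario's QTL.
#' @param reference_generations Generations pooled into the reference set.
#' @param selection `"random"` (default: design effects, not selection, drive
#'   the results) or `"ebv"` (truncation on phenotype-EBV) choice of
#'   next-generation parents.
#' @param store_haplotypes Keep marker haplotypes of reference generations
#'   (needed for LD tables).
#' @param sa_control Named list of overrides for [pair_inbreeding_opt()]
#'   (`t0`, `cooling`, `t_min`, `patience`, `sweep_moves`).
#' @return A `study_pop`: list with `animals` (tibble: `id`, `sire`, `dam`,
#'   `sex`, `generation`, `f`, `tbv`, `phenotype`, `set`), `genotypes` (named
#'   list of integer marker-dosage matrices per stored generation), `haplo`
#'   (marker haplotypes per reference generation, if requested), `trait`,
#'   `design`, `map`, `marker_idx`, `qtl_idx`.
#' @export
simulate_recent <- function(expanded, map, design, raw_effects, h2,
                            sigma_p2 = 1, n_sires = 50, n_dams = 3500,
                            n_gen = 10, litter = 5, mutation_rate = 2.5e-5,
                            marker_idx = marker_loci(map),
                            qtl_idx = qtl_loci(map),
                            reference_generations = NULL,
                            selection = c("random", "ebv"),
                            store_haplotypes = FALSE,
                            sa_control = list()) {
  designs <- c("random", "assortative_pos", "assortative_neg",
               "min_inbreeding", "max_inbreeding")
  if (!is.character(design) || length(design) != 1 || !design %in% designs)
    abort(paste0("Unknown design; use one of: ", paste(designs, collapse = ", ")),
          class = "matesim_config_error")
  selection <- match.arg(selection)
  stopifnot(length(raw_effects) == length(qtl_idx))
  if (is.null(reference_generations))
    reference_generations <- if (n_gen >= 4) 3:(n_gen - 1) else integer(0)
  pos <- map$pos_cM
  len <- map_length(map)
  males <- which(expanded$sex == "M")
  females <- which(expanded$sex == "F")
  if (length(males) < n_sires || length(females) < n_dams)
    abort("Expanded population cannot supply the requested parents.",
          class = "matesim_sim_error")
  keep <- c(sample(males, n_sires), sample(females, n_dams))
  cols <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  par_haplo <- expanded$haplo[, cols, drop = FALSE]
  n_par <- n_sires + n_dams
  par_id <- seq_len(n_par)
  par_sex <- rep(c("M", "F"), c(n_sires, n_dams))

  trait <- scale_trait(cpp_dosage(par_haplo, as.integer(qtl_idx)), raw_effects,
                       h2, sigma_p2)
  par_tbv <- drop(cpp_dosage(par_haplo, as.integer(qtl_idx)) %*% trait$effects)
  par_y <- phenotype(trait, par_tbv)
  K <- diag(0.5, n_par)
  dimnames(K) <- list(par_id, par_id)

  animals <- vector("list", n_gen + 1L)
  animals[[1]] <- tibble::tibble(
    id = par_id, sire = NA_integer_, dam = NA_integer_, sex = par_sex,
    generation = 0L, f = 0, tbv = par_tbv, phenotype = par_y,
    set = NA_character_)
  genotypes <- list()
  haplo_store <- list()
  next_id <- n_par + 1L
  sa <- utils::modifyList(list(t0 = 0.5, cooling = 0.9, t_min = 1e-4,
                               patience = 50), sa_control)

  for (g in seq_len(n_gen)) {
    sires <- par_id[par_sex == "M"]
    dams <- par_id[par_sex == "F"]
    plan <- switch(
      design,
      random = pair_random(sires, dams),
      assortative_pos = ,
      assortative_neg = {
        ebv <- estimate_ebv(setNames(par_y, par_id), h2)
        pair_assortative(sires, dams, ebv,
                         direction = if (design == "assortative_pos") "positive" else "negative")
      },
      min_inbreeding = ,
      max_inbreeding = pair_inbreeding_opt(
        sires, dams, K,
        objective = if (design == "min_inbreeding") "min" else "max",
        t0 = sa$t0, cooling = sa$cooling, t_min = sa$t_min,
        patience = sa$patience,
        sweep_moves = sa$sweep_moves %||% length(dams))
    )
    sire_of <- rep(plan$sire, each = litter)
    dam_of <- rep(plan$dam, each = litter)
    si <- match(sire_of, par_id)
    di <- match(dam_of, par_id)
    child <- drop_offspring(par_haplo, si, di, pos, len, mutation_rate)
    n_off <- length(si)
    off_id <- seq.int(next_id, length.out = n_off)
    next_id <- next_id + n_off
    off_sex <- ifelse(runif(n_off) < 0.5, "M", "F")
    off_tbv <- drop(cpp_dosage(child, as.integer(qtl_idx)) %*% trait$effects)
    off_y <- phenotype(trait, off_tbv)
    off_f <- K[cbind(si, di)]
    set <- if (g %in% reference_generations) "reference"
           else if (g == n_gen) "validation" else NA_character_
    animals[[g + 1L]] <- tibble::tibble(
      id = off_id, sire = sire_of, dam = dam_of, sex = off_sex,
      generation = g, f = off_f, tbv = off_tbv, phenotype = off_y, set = set)
    if (!is.na(set)) {
      genotypes[[as.character(g)]] <- cpp_dosage(child, as.integer(marker_idx))
      if (store_haplotypes && set == "reference")
        haplo_store[[as.character(g)]] <- child[marker_idx, , drop = FALSE]
    }
    if (g < n_gen) {
      m_idx <- which(off_sex == "M")
      f_idx <- which(off_sex == "F")
      if (length(m_idx) < n_sires || length(f_idx) < n_dams)
        abort("Offspring shortfall: not enough replacements of one sex.",
              class = "matesim_sim_error")
      if (selection == "random") {
        sel <- c(sample(m_idx, n_sires), sample(f_idx, n_dams))
      } else {
        ebv_off <- h2 * (off_y - mean(off_y))
        sel <- c(m_idx[order(-ebv_off[m_idx])][seq_len(n_sires)],
                 f_idx[order(-ebv_off[f_idx])][seq_len(n_dams)])
      }
      K <- propagate_kinship(K, si[sel], di[sel], off_id[sel])
      ccols <- as.vector(rbind(2L * sel - 1L, 2L * sel))
      par_haplo <- child[, ccols, drop = FALSE]
      par_id <- off_id[sel]
      par_sex <- rep(c("M", "F"), c(n_sires, n_dams))
      par_y <- off_y[sel]
    }
  }
  structure(
    list(animals = dplyr::bind_rows(animals), genotypes = genotypes,
         haplo = haplo_store, trait = trait, design = design, map = map,
         marker_idx = marker_idx, qtl_idx = qtl_idx, n_gen = n_gen,
         reference_generations = intersect(reference_generations, seq_len(n_gen))),
    class = "study_pop"
  )
}

#' @export
print.study_pop <- function(x, ...) {
  a <- x$animals
  cat(sprintf("<study_pop> design %s: %d animals over generations 0-%d (%d reference, %d validation), %d markers / %d QTL\n",
              x$design, nrow(a), x$n_gen,
              sum(a$set == "reference", na.rm = TRUE),
              sum(a$set == "validation", na.rm = TRUE),
              length(x$marker_idx), length(x$qtl_idx)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the pedigree of a study population
#'
#' CSV with one row per animal: id, sire, dam, sex, generation, inbreeding
#' coefficient, and reference/validation membership.
#'
#' @param study A `study_pop`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(study, path) {
  utils::write.csv(as.data.frame(study$animals), path, row.names = FALSE)
  invisible(path)
}
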