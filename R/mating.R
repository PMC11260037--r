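#' Pedigree kinship matrix (tabular method)
#'
#' Computes the additive relationship matrix A by the tabular method and
#' returns kinship = A / 2, so the diagonal is 0.5 * (1 + F) and the kinship
#' of a sire-dam pair equals the inbreeding coefficient of their progeny.
#' Founders (unknown parents) are taken as unrelated and non-inbred.
#'
#' @param ped Data frame with columns `id`, `sire`, `dam` (parent ids, `NA`
#'   when unknown), ordered parents-before-offspring.
#' @return Symmetric kinship matrix with `id` dimnames.
#' @export
kinship_matrix <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  id <- as.character(ped$id)
  n <- length(id)
  si <- match(as.character(ped$sire), id)
  di <- match(as.character(ped$dam), id)
  if (any(si >= seq_len(n), na.rm = TRUE) || any(di >= seq_len(n), na.rm = TRUE))
    abort("Pedigree must be sorted parents-before-offspring (no cycles).",
          class = "matesim_pedigree_error")
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + 0.5 * (if (!is.na(s) && !is.na(d)) A[s, d] else 0)
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (!is.na(s)) A[s, j] else 0) + (if (!is.na(d)) A[d, j] else 0))
      A[i, j] <- aij
      A[j, i] <- aij
    }
  }
  A / 2
}

#' Inbreeding coefficients from a kinship matrix
#' @param kin Kinship matrix from [kinship_matrix()].
#' @return Named numeric vector F = 2 * self-kinship - 1.
#' @export
inbreeding_from_kinship <- function(kin) 2 * diag(kin) - 1

# Near-equal dam counts per sire; remainder goes to the leading sires.
balanced_counts <- function(n_dams, n_sires) {
  base <- n_dams %/% n_sires
  extra <- n_dams %% n_sires
  rep(base, n_sires) + rep(c(1L, 0L), c(extra, n_sires - extra))
}

new_mate_plan <- function(sire, dam, design, kinship = NULL) {
  f <- if (is.null(kinship)) rep(NA_real_, length(dam)) else
    kinship[cbind(as.character(sire), as.character(dam))]
  plan <- tibble::tibble(sire = sire, dam = dam, exp_progeny_f = f)
  attr(plan, "design") <- design
  class(plan) <- c("mate_plan", class(plan))
  plan
}

#' Random mate allocation
#'
#' Shuffles the dams and deals them to the sires in near-equal blocks, so
#' every dam appears exactly once and sire usage differs by at most one.
#'
#' @param sires,dams Vectors of candidate ids.
#' @param kinship Optional kinship matrix (id dimnames) used to record the
#'   expected progeny inbreeding of each pair.
#' @return A `mate_plan` tibble: `sire`, `dam`, `exp_progeny_f`.
#' @export
pair_random <- function(sires, dams, kinship = NULL) {
  if (length(sires) < 1) abort("Need at least one sire.", class = "matesim_config_error")
  counts <- balanced_counts(length(dams), length(sires))
  new_mate_plan(rep(sires, counts), sample(dams), "random", kinship)
}

#' Assortative mate allocation on estimated breeding values
#'
#' Ranks sires and dams by EBV and matches blocks: under positive
#' assortment the best sire receives the best block of dams (descending);
#' under negative assortment the best sire receives the worst block
#' (ascending). Ties are broken by id, making the plan deterministic given
#' the EBVs.
#'
#' @param sires,dams Candidate ids.
#' @param ebv Named numeric vector of EBVs covering all candidates.
#' @param direction `"positive"` (like with like) or `"negative"`.
#' @inheritParams pair_random
#' @return A `mate_plan` tibble.
#' @export
pair_assortative <- function(sires, dams, ebv,
                             direction = c("positive", "negative"),
                             kinship = NULL) {
  direction <- match.arg(direction)
  es <- ebv[as.character(sires)]
  ed <- ebv[as.character(dams)]
  if (anyNA(es) || anyNA(ed))
    abort("EBVs missing for some candidates.", class = "matesim_config_error")
  s_ord <- sires[order(-es, sires)]
  d_ord <- if (direction == "positive") dams[order(-ed, dams)] else dams[order(ed, dams)]
  counts <- balanced_counts(length(dams), length(sires))
  new_mate_plan(rep(s_ord, counts), d_ord,
                paste0("assortative_", substr(direction, 1, 3)), kinship)
}

#' Mate allocation optimising progeny inbreeding by simulated annealing
#'
#' Searches balanced sire-dam allocations for the minimum (or maximum) mean
#' parental kinship, i.e. mean expected progeny inbreeding. The annealer is a
#' Metropolis scheme over feasibility-preserving moves (swap the sires of two
#' randomly chosen dams): improving moves are always accepted, worsening
#' moves with probability `exp(-delta / T)`. Temperature starts at 0.5 and is
#' lowered by a factor 0.9 after every sweep of `sweep_moves` proposals; the
#' best allocation seen is returned. Stops when the temperature falls below
#' `t_min` or after `patience` sweeps without improvement.
#'
#' @param sires,dams Candidate ids.
#' @param kinship Kinship matrix with id dimnames covering all candidates.
#' @param objective `"min"` or `"max"` mean progeny inbreeding.
#' @param t0 Initial temperature.
#' @param cooling Geometric cooling factor per sweep.
#' @param t_min Stopping temperature.
#' @param patience Sweeps without improvement before stopping.
#' @param sweep_moves Proposals per temperature level (default one expected
#'   touch per dam).
#' @param trace If `TRUE`, attach a sweep-level tibble (`sweep`,
#'   `temperature`, `objective`, `best`) as attribute `"trace"`.
#' @return A `mate_plan` tibble; the attained mean expected progeny
#'   inbreeding is in attribute `"objective"`.
#' @export
pair_inbreeding_opt <- function(sires, dams, kinship,
                                objective = c("min", "max"),
                                t0 = 0.5, cooling = 0.9, t_min = 1e-4,
                                patience = 50, sweep_moves = length(dams),
                                trace = FALSE) {
  objective <- match.arg(objective)
  if (!length(sires) || !length(dams))
    abort("Empty candidate set.", class = "matesim_config_error")
  ks <- kinship[as.character(sires), as.character(dams), drop = FALSE]
  n_d <- length(dams)
  n_s <- length(sires)
  sgn <- if (objective == "min") 1 else -1
  counts <- balanced_counts(n_d, n_s)
  assign <- sample(rep(seq_len(n_s), counts)) # sire index per dam
  obj <- mean(ks[cbind(assign, seq_len(n_d))])
  best <- assign
  best_obj <- obj
  tr <- list()
  if (n_s > 1L) {
    temp <- t0
    sweep <- 0L
    stale <- 0L
    while (temp >= t_min && stale < patience) {
      sweep <- sweep + 1L
      d1 <- sample.int(n_d, sweep_moves, replace = TRUE)
      d2 <- sample.int(n_d, sweep_moves, replace = TRUE)
      u <- runif(sweep_moves)
      improved <- FALSE
      for (m in seq_len(sweep_moves)) {
        a <- d1[m]; b <- d2[m]
        s1 <- assign[a]; s2 <- assign[b]
        if (s1 == s2) next
        delta <- sgn * (ks[s2, a] + ks[s1, b] - ks[s1, a] - ks[s2, b]) / n_d
        if (delta < 0 || u[m] < exp(-delta / temp)) {
          assign[a] <- s2
          assign[b] <- s1
          obj <- obj + sgn * delta
          if (sgn * obj < sgn * best_obj - 1e-15) {
            best <- assign
            best_obj <- obj
            improved <- TRUE
          }
        }
      }
      stale <- if (improved) 0L else stale + 1L
      if (trace) tr[[sweep]] <- c(sweep = sweep, temperature = temp,
                                  objective = obj, best = best_obj)
      temp <- temp * cooling
    }
  }
  plan <- new_mate_plan(sires[best], dams, paste0(objective, "_inbreeding"), kinship)
  attr(plan, "objective") <- best_obj
  if (trace && length(tr))
    attr(plan, "trace") <- tibble::as_tibble(as.data.frame(do.call(rbind, tr)))
  plan
}

#' Validate a mate plan
#'
#' Checks the structural invariants: every dam exactly once, sire usage
#' near-equal (counts differ by at most one), and expected progeny inbreeding
#' within `[0, 1]` where recorded.
#'
#' @param plan A `mate_plan`.
#' @param sires,dams The candidate sets the plan was built from.
#' @return `TRUE` invisibly; aborts on violation.
#' @export
validate_mate_plan <- function(plan, sires, dams) {
  if (!setequal(plan$dam, dams) || anyDuplicated(plan$dam))
    abort("Every dam must appear exactly once.", class = "matesim_plan_error")
  use <- table(factor(plan$sire, levels = sires))
  if (diff(range(use)) > 1)
    abort("Sire usage must be near-equal.", class = "matesim_plan_error")
  f <- plan$exp_progeny_f
  if (any(!is.na(f) & (f < 0 | f > 1)))
    abort("Expected progeny inbreeding out of [0, 1].", class = "matesim_plan_error")
  invisible(TRUE)
}

#' Write a mate plan as CSV
#' @param plan A `mate_plan`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mate_plan <- function(plan, path) {
  utils::write.csv(as.data.frame(plan), path, row.names = FALSE)
  invisible(path)
}
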