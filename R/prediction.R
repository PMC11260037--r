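#' Estimate breeding values for mate ranking
#'
#' EBVs used to rank candidates in the assortative designs. The default
#' `"phenotype"` method is the heritability-regressed phenotype deviation
#' `EBV = h2 * (y - mean(y))`; `"pedigree_blup"` solves the animal-model
#' mixed-model equations with the pedigree relationship matrix (Henderson)
#' and variance ratio `(1 - h2) / h2` — intended for small candidate sets.
#'
#' @param phenotypes Named numeric vector of phenotypes (names are animal
#'   ids; `NA` allowed under `"pedigree_blup"` for unphenotyped animals).
#' @param h2 Narrow-sense heritability.
#' @param method `"phenotype"` or `"pedigree_blup"`.
#' @param pedigree Data frame (`id`, `sire`, `dam`), parents before
#'   offspring, covering all phenotyped animals; required for
#'   `"pedigree_blup"`.
#' @return Named numeric vector of EBVs (one per pedigree animal for
#'   `"pedigree_blup"`, one per phenotype otherwise).
#' @export
estimate_ebv <- function(phenotypes, h2,
                         method = c("phenotype", "pedigree_blup"),
                         pedigree = NULL) {
  method <- match.arg(method)
  if (method == "phenotype") {
    if (anyNA(phenotypes))
      abort("Missing phenotypes under method = \"phenotype\".",
            class = "matesim_config_error")
    return(h2 * (phenotypes - mean(phenotypes)))
  }
  if (is.null(pedigree)) abort("`pedigree` required for pedigree BLUP.")
  id <- as.character(pedigree$id)
  y <- phenotypes[id]
  obs <- which(!is.na(y))
  if (!length(obs)) abort("No phenotyped animals in the pedigree.")
  if (h2 == 0) return(setNames(rep(0, length(id)), id))
  A <- 2 * kinship_matrix(pedigree)
  lambda_a <- (1 - h2) / h2
  n <- length(id)
  Z <- matrix(0, length(obs), n)
  Z[cbind(seq_along(obs), obs)] <- 1
  ones <- rep(1, length(obs))
  C <- rbind(
    cbind(length(obs), t(ones) %*% Z),
    cbind(t(Z) %*% ones, crossprod(Z) + lambda_a * solve(A))
  )
  rhs <- c(sum(y[obs]), drop(t(Z) %*% y[obs]))
  sol <- solve(C, rhs)
  setNames(sol[-1], id)
}

#' Per-marker effect variance and ridge factor from base parameters
#'
#' Allocates the genetic variance `h2 * sigma_p2` evenly over markers via
#' `sigma_g2 = h2 * sigma_p2 / sum(2 p_j (1 - p_j))` and returns the
#' SNP-BLUP ridge factor `lambda = sigma_e2 / sigma_g2`. The simulation
#' knows its true variance components, so no REML step is needed.
#'
#' @param h2 Heritability.
#' @param sigma_p2 Phenotypic variance.
#' @param freqs Allele frequencies of the (segregating) markers entering the
#'   fit.
#' @return List with `sigma_g2` and `lambda`.
#' @export
default_lambda <- function(h2, sigma_p2, freqs) {
  het <- sum(2 * freqs * (1 - freqs))
  if (het <= 0)
    abort("All markers fixed: cannot allocate marker variance.",
          class = "matesim_config_error")
  if (h2 <= 0 || h2 > 1) abort("`h2` must lie in (0, 1].", class = "matesim_config_error")
  sigma_g2 <- h2 * sigma_p2 / het
  list(sigma_g2 = sigma_g2, lambda = (1 - h2) * sigma_p2 / sigma_g2)
}

#' Ridge-regression BLUP (SNP-BLUP) fit
#'
#' Fits `y = 1 mu + X g + e` with a common ridge penalty on all marker
#' effects by solving the two-block mixed-model equations
#' `[1'1, 1'X; X'1, X'X + I lambda] [mu; g] = [1'y; X'y]` with a direct
#' dense solve (unique for `lambda > 0`). Zero-variance (fixed) marker
#' columns are dropped before fitting and recorded in the fit.
#'
#' @param X Integer/numeric dosage matrix (animals x markers, entries
#'   0/1/2), optionally with column names.
#' @param y Phenotype vector.
#' @param lambda Ridge factor `sigma_e2 / sigma_g2` (> 0), e.g. from
#'   [default_lambda()].
#' @return An `rrblup_fit`: list with `mu`, `effects` (named by marker),
#'   `lambda`, `kept` (column indices fitted), `n`, `m`.
#' @export
rrblup_fit <- function(X, y, lambda) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (nrow(X) < 2) abort("Need at least two records.", class = "matesim_config_error")
  if (!is.finite(lambda) || lambda <= 0)
    abort("`lambda` must be positive and finite.", class = "matesim_config_error")
  if (is.null(colnames(X))) colnames(X) <- paste0("m", seq_len(ncol(X)))
  rng <- matrixStats_colRange(X)
  kept <- which(rng[1, ] != rng[2, ])
  if (!length(kept)) abort("All marker columns are fixed.", class = "matesim_config_error")
  Xk <- X[, kept, drop = FALSE]
  storage.mode(Xk) <- "double"
  sol <- rrblup_solve(crossprod(Xk), drop(crossprod(Xk, y)), colSums(Xk),
                      nrow(Xk), sum(y), lambda)
  structure(
    list(mu = sol$mu, effects = setNames(sol$effects, colnames(Xk)),
         lambda = lambda, kept = unname(kept), n = nrow(Xk), m = ncol(Xk)),
    class = "rrblup_fit"
  )
}

# Direct dense solve of the two-block mixed-model equations from accumulated
# cross-products (lets callers pool huge reference sets without ever
# materialising the stacked dosage matrix).
rrblup_solve <- function(XtX, Xty, csum, n, sum_y, lambda) {
  m <- ncol(XtX)
  C <- rbind(c(n, csum), cbind(csum, XtX + diag(lambda, m)))
  rhs <- c(sum_y, Xty)
  sol <- tryCatch(solve(C, rhs), error = function(e)
    abort(paste0("Mixed-model equations are numerically singular: ", conditionMessage(e)),
          class = "matesim_numeric_error"))
  list(mu = unname(sol[1]), effects = unname(sol[-1]))
}

# colRange without a matrixStats dependency
matrixStats_colRange <- function(X) {
  rbind(apply(X, 2, min), apply(X, 2, max))
}

#' @export
print.rrblup_fit <- function(x, ...) {
  cat(sprintf("<rrblup_fit> n = %d, markers = %d, lambda = %.4g, mu = %.4g\n",
              x$n, x$m, x$lambda, x$mu))
  invisible(x)
}

#' @describeIn rrblup_fit Marker effect estimates as a tibble (`marker`,
#'   `estimate`).
#' @param x An `rrblup_fit`.
#' @param ... Unused.
#' @export
tidy.rrblup_fit <- function(x, ...) {
  tibble::tibble(marker = names(x$effects), estimate = unname(x$effects))
}

#' @describeIn rrblup_fit One-row model summary (`n`, `n_markers`, `lambda`,
#'   `mu`).
#' @export
glance.rrblup_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_markers = x$m, lambda = x$lambda, mu = x$mu)
}

#' Genomic estimated breeding values
#'
#' `GEBV = X g_hat` (no intercept, matching the SNP-BLUP prediction
#' formula); applied to reference and validation animals alike.
#'
#' @param X Dosage matrix whose columns match the markers the fit was
#'   estimated on (extra columns dropped via the fit's `kept` index).
#' @param fit An `rrblup_fit`.
#' @return Numeric GEBV vector.
#' @export
gebv <- function(X, fit) {
  stopifnot(inherits(fit, "rrblup_fit"))
  if (ncol(X) != fit$m) {
    if (max(fit$kept) > ncol(X))
      abort("Dosage matrix does not cover the fitted markers.",
            class = "matesim_config_error")
    X <- X[, fit$kept, drop = FALSE]
  }
  storage.mode(X) <- "double"
  drop(X %*% fit$effects)
}
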