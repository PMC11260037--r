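# Independent oracles used across tests. These re-derive expected values by
# routes that share no code with the implementation they check.

# Recursive path-counting kinship (memoised). ped: data.frame id/sire/dam,
# parents before offspring, ids are characters or coercible.
kinship_oracle <- function(ped) {
  id <- as.character(ped$id)
  n <- length(id)
  si <- match(as.character(ped$sire), id)
  di <- match(as.character(ped$dam), id)
  memo <- new.env(parent = emptyenv())
  kin <- function(i, j) {
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == j) {
      0.5 * (1 + (if (!is.na(si[i]) && !is.na(di[i])) kin(si[i], di[i]) else 0))
    } else {
      # j is the younger animal (larger index): decompose through its parents
      0.5 * ((if (!is.na(si[j])) kin(i, si[j]) else 0) +
               (if (!is.na(di[j])) kin(i, di[j]) else 0))
    }
    memo[[key]] <- v
    v
  }
  K <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) for (j in i:n) K[i, j] <- K[j, i] <- kin(i, j)
  K
}

# GBLUP route for SNP-BLUP predictions: GLS intercept on V = XX' + lambda I,
# BLUP u = XX' V^-1 (y - mu). Equivalent to the mixed-model equations by the
# Woodbury identity, computed on the n x n scale.
gblup_oracle <- function(X, y, lambda) {
  G <- tcrossprod(X)
  V <- G + diag(lambda, nrow(X))
  Vi <- solve(V)
  one <- rep(1, nrow(X))
  mu <- drop((t(one) %*% Vi %*% y) / (t(one) %*% Vi %*% one))
  list(mu = mu, gebv = drop(G %*% Vi %*% (y - mu)))
}

# Ridge regression via augmented least squares solved by QR: rows
# [1 X; 0 sqrt(lambda) I] against [y; 0]. Intercept unpenalised.
ridge_qr_oracle <- function(X, y, lambda) {
  m <- ncol(X)
  A <- rbind(cbind(1, X), cbind(0, diag(sqrt(lambda), m)))
  b <- c(y, rep(0, m))
  qr.solve(A, b)
}

# All balanced assignments of dams to n_s sires (multiset permutations of
# rep(1:n_s, counts)); returns a matrix with one assignment per row.
balanced_allocations <- function(n_s, n_d) {
  counts <- {
    base <- n_d %/% n_s; extra <- n_d %% n_s
    rep(base, n_s) + rep(c(1L, 0L), c(extra, n_s - extra))
  }
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, nrow = 1))
    out <- list()
    for (u in unique(v)) {
      rest <- v[-match(u, v)]
      sub <- perms(rest)
      out[[length(out) + 1]] <- cbind(u, sub)
    }
    do.call(rbind, out)
  }
  unname(perms(rep(seq_len(n_s), counts)))
}

# Random genotype matrix with every column segregating.
random_dosage <- function(n, m, maf_min = 0.1) {
  repeat {
    p <- runif(m, maf_min, 1 - maf_min)
    X <- sapply(p, function(pp) rbinom(n, 2, pp))
    if (is.matrix(X) && all(apply(X, 2, var) > 0)) return(X)
  }
}

# Small-but-complete scenario configuration for fast end-to-end runs.
tiny_cfg <- function(design = "random", h2 = 0.3, n_markers = 80, n_qtl = 10,
                     n_replicates = 1, master_seed = 99, n_sires = 8,
                     n_dams = 48, ...) {
  scenario_config(n_markers = n_markers, n_qtl = n_qtl, h2 = h2,
                  design = design, n_replicates = n_replicates,
                  scale = 0.04, n_sires = n_sires, n_dams = n_dams, litter = 3,
                  exp_sires = 20, exp_dams = 100, exp_max_dams = 250,
                  master_seed = master_seed, ...)
}
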