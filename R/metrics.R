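#' Prediction accuracy
#'
#' Pearson correlation between true and genomically estimated breeding
#' values.
#'
#' @param tbv,gebv Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
accuracy <- function(tbv, gebv) {
  if (length(tbv) != length(gebv) || length(tbv) < 3)
    abort("Need equal-length vectors of at least 3 values.",
          class = "matesim_config_error")
  if (var(tbv) == 0 || var(gebv) == 0)
    abort("Zero variance: accuracy undefined for this replicate.",
          class = "matesim_degenerate_metric")
  cor(tbv, gebv)
}

#' Bias of genomic prediction
#'
#' Ordinary least-squares slope of TBV regressed on GEBV; an unbiased
#' prediction has expected slope one (values below one indicate inflated
#' GEBV spread, above one shrunken spread).
#'
#' @param tbv,gebv Numeric vectors of equal length (>= 3).
#' @return One-row tibble with `slope` and its standard error `se`.
#' @export
bias_slope <- function(tbv, gebv) {
  if (length(tbv) != length(gebv) || length(tbv) < 3)
    abort("Need equal-length vectors of at least 3 values.",
          class = "matesim_config_error")
  vg <- var(gebv)
  if (vg == 0)
    abort("Zero GEBV variance: slope undefined.", class = "matesim_degenerate_metric")
  n <- length(tbv)
  b <- stats::cov(gebv, tbv) / vg
  a <- mean(tbv) - b * mean(gebv)
  res <- tbv - a - b * gebv
  se <- sqrt(sum(res^2) / (n - 2) / ((n - 1) * vg))
  tibble::tibble(slope = b, se = se)
}

#' Pairwise linkage disequilibrium r2
#'
#' Squared allelic correlation `r2 = D^2 / (f(A) f(a) f(B) f(b))` with
#' `D = f(AB) - f(A) f(B)`, frequencies counted over phased haplotypes.
#'
#' @param hapA,hapB 0/1 allele vectors over the same haplotypes.
#' @return r2 in `[0, 1]`; `NA` with a warning if either locus is fixed.
#' @export
ld_r2_pair <- function(hapA, hapB) {
  stopifnot(length(hapA) == length(hapB))
  pA <- mean(hapA)
  pB <- mean(hapB)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    warn("Fixed locus: r2 undefined, pair excluded.")
    return(NA_real_)
  }
  D <- mean(hapA * hapB) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Distance bins for LD summaries
#'
#' The standard half-open (lo, hi] centimorgan bins used for r2 decay
#' tables: (0-0.05], (0.05-0.1], (0.1-0.2], ... (0.9-1], then 1-cM bins out
#' to 5 cM. Pairs farther apart than the largest edge are excluded.
#'
#' @return Tibble with `lo`, `hi` and a `bin` label.
#' @export
ld_bins <- function() {
  edges <- c(0, 0.05, 0.1, seq(0.2, 1, by = 0.1), 2, 3, 4, 5)
  tibble::tibble(
    lo = edges[-length(edges)], hi = edges[-1],
    bin = sprintf("(%g-%g]", edges[-length(edges)], edges[-1])
  )
}

#' Binned LD r2 table for one generation
#'
#' Computes r2 for every segregating marker pair whose map distance is at
#' most the largest bin edge and averages within distance bins, mirroring
#' the canonical decay-table layout (bin, pair count, mean r2).
#'
#' @param haplo Marker haplotypes: an L_m x 2n raw or 0/1 matrix (one row
#'   per marker, [build_genome_map()] order), or a `haplo_pop` (marker rows
#'   are then taken via `marker_idx`).
#' @param positions Marker positions in cM (length L_m).
#' @param bins Bin tibble as from [ld_bins()].
#' @param generation Generation label attached to the output.
#' @param marker_idx Rows to use when `haplo` is a `haplo_pop`.
#' @return Tibble with `generation`, `bin`, `lo`, `hi`, `n_pairs`,
#'   `mean_r2` (NA for empty bins).
#' @export
ld_table <- function(haplo, positions, bins = ld_bins(), generation = NA_integer_,
                     marker_idx = NULL) {
  if (inherits(haplo, "haplo_pop")) {
    if (is.null(marker_idx)) abort("Supply `marker_idx` for a haplo_pop input.")
    haplo <- haplo$haplo[marker_idx, , drop = FALSE]
  }
  H <- haplo
  if (is.raw(H)) H <- matrix(as.integer(H), nrow(H), ncol(H))
  stopifnot(nrow(H) == length(positions))
  pr <- ld_pair_r2(H, positions, max_dist = max(bins$hi))
  cut_idx <- findInterval(pr$dist, c(bins$lo[1], bins$hi), left.open = TRUE,
                          rightmost.closed = FALSE) # (lo, hi] half-open bins
  keep <- cut_idx >= 1 & cut_idx <= nrow(bins) & pr$dist > bins$lo[1]
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin_i = cut_idx[keep], r2 = pr$r2[keep]),
                    .data$bin_i),
    n_pairs = dplyr::n(), mean_r2 = mean(.data$r2), .groups = "drop")
  out <- dplyr::left_join(
    dplyr::mutate(bins, bin_i = dplyr::row_number(), generation = generation),
    agg, by = "bin_i")
  out <- dplyr::mutate(out,
                       n_pairs = dplyr::coalesce(.data$n_pairs, 0L))
  res <- dplyr::select(out, "generation", "bin", "lo", "hi", "n_pairs", "mean_r2")
  class(res) <- c("ld_table", class(res))
  res
}

# All segregating-pair r2 values within max_dist. H: markers x haplotypes
# 0/1 integer matrix. Returns list(dist, r2).
ld_pair_r2 <- function(H, positions, max_dist) {
  n2 <- ncol(H)
  p <- rowMeans(H)
  seg <- which(p > 0 & p < 1)
  if (length(seg) < 2) return(list(dist = numeric(0), r2 = numeric(0)))
  Hs <- H[seg, , drop = FALSE]
  ps <- p[seg]
  pos <- positions[seg]
  storage.mode(Hs) <- "double"
  CC <- tcrossprod(Hs) / n2 # f(AB) for all pairs
  m <- length(seg)
  ii <- rep.int(seq_len(m - 1), (m - 1):1)
  jj <- sequence((m - 1):1) + ii
  d <- pos[jj] - pos[ii]
  keep <- d <= max_dist & d > 0
  ii <- ii[keep]; jj <- jj[keep]; d <- d[keep]
  fAB <- CC[cbind(ii, jj)]
  D <- fAB - ps[ii] * ps[jj]
  r2 <- D^2 / (ps[ii] * (1 - ps[ii]) * ps[jj] * (1 - ps[jj]))
  list(dist = d, r2 = r2)
}

#' LD decay tables for the reference generations of a study
#'
#' Applies [ld_table()] to each stored reference generation of a
#' [simulate_recent()] run (requires `store_haplotypes = TRUE`).
#'
#' @param study A `study_pop` with stored haplotypes.
#' @param bins Bin tibble as from [ld_bins()].
#' @return An `ld_table` tibble with one block per reference generation.
#' @export
ld_decay <- function(study, bins = ld_bins()) {
  if (!length(study$haplo))
    abort("Study was run without `store_haplotypes = TRUE`.",
          class = "matesim_config_error")
  pos <- study$map$pos_cM[study$marker_idx]
  res <- purrr::map(names(study$haplo), function(g)
    ld_table(study$haplo[[g]], pos, bins, generation = as.integer(g)))
  out <- dplyr::bind_rows(res)
  class(out) <- c("ld_table", class(out))
  out
}

#' Mean pairwise r2 up to a distance cutoff
#'
#' Single-number LD summary: the unbinned mean r2 over all segregating
#' marker pairs at most `max_dist` cM apart, pooled over the stored
#' reference generations (pair-count weighted).
#'
#' @param study A `study_pop` with stored haplotypes.
#' @param max_dist Distance cutoff in cM.
#' @return Mean r2.
#' @export
ld_mean_r2 <- function(study, max_dist = 5) {
  if (!length(study$haplo))
    abort("Study was run without `store_haplotypes = TRUE`.",
          class = "matesim_config_error")
  pos <- study$map$pos_cM[study$marker_idx]
  tot <- 0; cnt <- 0
  for (g in names(study$haplo)) {
    H <- study$haplo[[g]]
    H <- matrix(as.integer(H), nrow(H), ncol(H))
    pr <- ld_pair_r2(H, pos, max_dist)
    tot <- tot + sum(pr$r2)
    cnt <- cnt + length(pr$r2)
  }
  tot / cnt
}

#' Replicate summary: mean and standard error
#'
#' @param values Per-replicate statistics.
#' @return One-row tibble with `mean`, `se` (sample SD over sqrt of the
#'   replicate count; 0 with a warning for a single replicate) and
#'   `n_replicates`.
#' @export
summarize_replicates <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) abort("Need at least one replicate.", class = "matesim_config_error")
  if (n == 1) {
    warn("Single replicate: standard error reported as 0.")
    return(tibble::tibble(mean = values, se = 0, n_replicates = 1L))
  }
  tibble::tibble(mean = mean(values), se = sd(values) / sqrt(n), n_replicates = n)
}

#' Write an LD table as CSV
#' @param ld An `ld_table` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ld_table <- function(ld, path) {
  utils::write.csv(as.data.frame(ld), path, row.names = FALSE)
  invisible(path)
}
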