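#' Build a genome map of equally spaced markers and randomly placed QTL
#'
#' Lays out a single chromosome of `length_cM` centimorgans carrying
#' `n_markers` bi-allelic markers at exactly equal spacing (`length_cM /
#' n_markers`, the first marker one spacing in from the origin) and `n_qtl`
#' QTL at uniform random positions on `(0, length_cM]`. QTL never coincide
#' with a marker position: the genomic predictor sees markers only and must
#' exploit marker-QTL linkage disequilibrium. Positions that collide with a
#' marker or another QTL are resampled.
#'
#' @param n_markers Number of markers (>= 2).
#' @param n_qtl Number of QTL (>= 1).
#' @param length_cM Chromosome length in centimorgans.
#' @return A `genome_map`: a tibble with one row per locus, columns `id`,
#'   `pos_cM` and `role` (`"marker"` or `"qtl"`), sorted by position, with the
#'   chromosome length in attribute `length_cM`. Row order is the locus order
#'   used by all haplotype matrices.
#' @examples
#' set.seed(1)
#' map <- build_genome_map(350, 50)
#' diff(dplyr::filter(map, role == "marker")$pos_cM)[1] # 100/350
#' @export
build_genome_map <- function(n_markers, n_qtl, length_cM = 100) {
  if (length(n_markers) != 1 || is.na(n_markers) || n_markers < 2)
    abort("`n_markers` must be a single count >= 2.", class = "matesim_config_error")
  if (length(n_qtl) != 1 || is.na(n_qtl) || n_qtl < 1)
    abort("`n_qtl` must be a single count >= 1.", class = "matesim_config_error")
  if (length(length_cM) != 1 || is.na(length_cM) || length_cM <= 0)
    abort("`length_cM` must be positive.", class = "matesim_config_error")
  marker_pos <- seq_len(n_markers) * (length_cM / n_markers)
  qtl_pos <- numeric(0)
  while (length(qtl_pos) < n_qtl) {
    cand <- runif(n_qtl - length(qtl_pos), 0, length_cM)
    cand <- cand[!(cand %in% marker_pos) & !(cand %in% qtl_pos) & cand > 0]
    qtl_pos <- c(qtl_pos, cand)
  }
  map <- tibble::tibble(
    id = c(sprintf("M%04d", seq_len(n_markers)), sprintf("Q%04d", seq_len(n_qtl))),
    pos_cM = c(marker_pos, qtl_pos),
    role = rep(c("marker", "qtl"), c(n_markers, n_qtl))
  )
  map <- dplyr::arrange(map, .data$pos_cM)
  attr(map, "length_cM") <- length_cM
  class(map) <- c("genome_map", class(map))
  map
}

#' Locus indices by role
#'
#' Row indices of a [build_genome_map()] map (equivalently haplotype-matrix
#' row indices) for marker or QTL loci.
#'
#' @param map A `genome_map`.
#' @return Integer vector of locus indices.
#' @export
marker_loci <- function(map) which(map$role == "marker")

#' @rdname marker_loci
#' @export
qtl_loci <- function(map) which(map$role == "qtl")

map_length <- function(map) attr(map, "length_cM")

#' Sample QTL allele-substitution effects
#'
#' Effect magnitudes are drawn from a gamma distribution (shape 0.4 by
#' default, the canonical heavy-tailed choice for QTL effect spectra: many
#' small effects, few large ones) and signs are assigned +/- with equal
#' probability. The gamma scale is irrelevant because effects are rescaled to
#' the target genetic variance by [scale_trait()].
#'
#' @param n_qtl Number of effects.
#' @param shape Gamma shape parameter.
#' @param scale Gamma scale parameter.
#' @return Numeric vector of signed effects.
#' @export
sample_qtl_effects <- function(n_qtl, shape = 0.4, scale = 1) {
  if (length(n_qtl) != 1 || is.na(n_qtl) || n_qtl < 1)
    abort("`n_qtl` must be a single count >= 1.", class = "matesim_config_error")
  if (shape <= 0) abort("`shape` must be positive.", class = "matesim_config_error")
  mag <- rgamma(n_qtl, shape = shape, scale = scale)
  sgn <- ifelse(runif(n_qtl) < 0.5, -1, 1)
  mag * sgn
}

#' Scale QTL effects to a target heritability
#'
#' Multiplies raw QTL effects by the single constant that makes the variance
#' of the true breeding value (TBV = dosage %*% effects) over the supplied
#' founder genotypes equal `h2 * sigma_p2`, and stores the residual variance
#' `(1 - h2) * sigma_p2`. Scaling in the founder cohort anchors the
#' heritability where phenotypes are first recorded.
#'
#' @param founder_genotypes Integer matrix of QTL dosages (individuals x QTL,
#'   entries 0/1/2).
#' @param raw_effects Unscaled QTL effects, one per column.
#' @param h2 Narrow-sense heritability in `[0, 1]`.
#' @param sigma_p2 Phenotypic variance.
#' @return A `trait_model`: list with scaled `effects`, `h2`, `sigma_p2`,
#'   `sigma_e2` and the applied `scale_factor`.
#' @export
scale_trait <- function(founder_genotypes, raw_effects, h2, sigma_p2 = 1) {
  stopifnot(is.matrix(founder_genotypes), ncol(founder_genotypes) == length(raw_effects))
  if (h2 < 0 || h2 > 1) abort("`h2` must lie in [0, 1].", class = "matesim_config_error")
  if (sigma_p2 <= 0) abort("`sigma_p2` must be positive.", class = "matesim_config_error")
  raw_tbv <- drop(founder_genotypes %*% raw_effects)
  v <- var(raw_tbv)
  if (!is.finite(v) || v <= 0)
    abort("All QTL are fixed in the founder cohort: raw TBV variance is zero. Resample QTL positions or effects.",
          class = "matesim_degenerate_trait")
  cf <- sqrt(h2 * sigma_p2 / v)
  structure(
    list(effects = raw_effects * cf, h2 = h2, sigma_p2 = sigma_p2,
         sigma_e2 = (1 - h2) * sigma_p2, scale_factor = cf),
    class = "trait_model"
  )
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("<trait_model> %d QTL, h2 = %.3g, sigma_p2 = %.3g, sigma_e2 = %.3g\n",
              length(x$effects), x$h2, x$sigma_p2, x$sigma_e2))
  invisible(x)
}

#' True breeding values from QTL dosages
#'
#' @param qtl_genotypes Integer matrix of QTL dosages (individuals x QTL).
#' @param trait A `trait_model` from [scale_trait()].
#' @return Numeric TBV vector.
#' @export
true_breeding_values <- function(qtl_genotypes, trait) {
  stopifnot(inherits(trait, "trait_model"))
  drop(qtl_genotypes %*% trait$effects)
}

#' Phenotypes as TBV plus normal residual
#'
#' Adds independent `N(0, sigma_e2)` residuals to true breeding values.
#'
#' @param trait A `trait_model`.
#' @param tbv TBV vector.
#' @return Numeric phenotype vector.
#' @export
phenotype <- function(trait, tbv) {
  stopifnot(inherits(trait, "trait_model"))
  if (trait$sigma_e2 < 0) abort("Residual variance must be non-negative.")
  tbv + rnorm(length(tbv), 0, sqrt(trait$sigma_e2))
}

#' Write a locus table
#'
#' Tab-delimited locus table (chrom, id, position in cM, role), a PLINK-style
#' .map layout extended with the role column.
#'
#' @param map A `genome_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_locus_table <- function(map, path) {
  out <- data.frame(chrom = 1L, id = map$id, pos_cM = map$pos_cM, role = map$role)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
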