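#' Construct a phased haplotype population
#'
#' The container for one generation of phased genotypes. Haplotypes are held
#' as an L x 2n raw matrix (loci in rows, in [build_genome_map()] order;
#' columns 2i-1 and 2i are the two strands of individual i, alleles 0/1).
#'
#' @param haplo L x 2n raw (or 0/1 integer) matrix of alleles.
#' @param sex Character vector of `"M"`/`"F"`, length n.
#' @param generation Generation index.
#' @param id Optional individual identifiers (default `1:n`).
#' @param sire,dam Optional parent identifiers (`NA` for founders).
#' @return A `haplo_pop` object.
#' @export
haplo_pop <- function(haplo, sex, generation = 0L, id = NULL,
                      sire = NULL, dam = NULL) {
  if (!is.matrix(haplo)) abort("`haplo` must be a matrix.")
  if (!is.raw(haplo)) {
    stopifnot(all(haplo %in% c(0L, 1L)))
    haplo <- matrix(as.raw(haplo), nrow(haplo), ncol(haplo))
  }
  n <- ncol(haplo) / 2
  if (n != floor(n)) abort("`haplo` must have an even number of columns (2 per individual).")
  if (length(sex) != n) abort("`sex` must have one entry per individual.")
  if (!all(sex %in% c("M", "F"))) abort("`sex` entries must be \"M\" or \"F\".")
  structure(
    list(haplo = haplo, sex = as.character(sex),
         generation = as.integer(generation),
         id = if (is.null(id)) seq_len(n) else id,
         sire = if (is.null(sire)) rep(NA_integer_, n) else sire,
         dam = if (is.null(dam)) rep(NA_integer_, n) else dam),
    class = "haplo_pop"
  )
}

#' @export
print.haplo_pop <- function(x, ...) {
  cat(sprintf("<haplo_pop> generation %d: %d individuals (%d M / %d F), %d loci\n",
              x$generation, n_individuals(x), sum(x$sex == "M"),
              sum(x$sex == "F"), nrow(x$haplo)))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `haplo_pop`.
#' @return Integer count.
#' @export
n_individuals <- function(pop) ncol(pop$haplo) %/% 2L

#' Per-locus allele frequency
#' @param pop A `haplo_pop`.
#' @return Numeric vector, frequency of allele 1 at each locus.
#' @export
allele_freq <- function(pop) cpp_allele_freq(pop$haplo)

#' Indices of segregating loci
#'
#' Loci whose minor allele frequency is strictly positive in the population.
#' Fixed loci carry no information and are excluded from prediction and LD.
#'
#' @param pop A `haplo_pop`, or a raw/integer haplotype matrix.
#' @return Integer vector of locus (row) indices.
#' @export
segregating_loci <- function(pop) {
  p <- if (inherits(pop, "haplo_pop")) allele_freq(pop) else {
    h <- pop
    if (!is.raw(h)) h <- matrix(as.raw(h), nrow(h), ncol(h))
    cpp_allele_freq(h)
  }
  which(p > 0 & p < 1)
}

#' Genotype dosages
#'
#' Counts of allele 1 (0/1/2) per individual at the requested loci.
#'
#' @param pop A `haplo_pop`.
#' @param loci Locus (row) indices; default all.
#' @return Integer matrix, individuals x loci.
#' @export
dosage <- function(pop, loci = NULL) {
  if (is.null(loci)) loci <- seq_len(nrow(pop$haplo))
  cpp_dosage(pop$haplo, as.integer(loci))
}

#' One meiosis
#'
#' Produces a single gamete from a parent under the Haldane crossover model
#' (no interference): crossover count ~ Poisson(length_cM / 100), breakpoints
#' uniform, starting strand random; each locus then mutates (allele flip)
#' independently with probability `mutation_rate`.
#'
#' @param parent L x 2 matrix (raw or 0/1) of the parent's two strands.
#' @param map A `genome_map`, or a numeric vector of locus positions in cM
#'   (then `length_cM` must be given).
#' @param mutation_rate Per-locus, per-generation allele flip probability.
#' @param length_cM Chromosome length when `map` is a bare position vector.
#' @return Integer 0/1 gamete vector of length L.
#' @export
meiosis <- function(parent, map, mutation_rate = 0, length_cM = NULL) {
  pos <- if (inherits(map, "genome_map")) map$pos_cM else as.numeric(map)
  len <- if (inherits(map, "genome_map")) map_length(map) else length_cM
  if (is.null(len)) abort("Supply `length_cM` when `map` is a position vector.")
  if (!is.raw(parent)) parent <- matrix(as.raw(parent), nrow(parent), ncol(parent))
  stopifnot(ncol(parent) == 2, nrow(parent) == length(pos))
  as.integer(cpp_gametes(parent, 1L, pos, len, mutation_rate))
}

# Internal: drop one offspring cohort. Returns the L x 2N raw matrix with
# paternal gametes in odd columns.
drop_offspring <- function(parents_haplo, sire_idx, dam_idx, pos, length_cM,
                           mutation_rate) {
  cpp_drop_offspring(parents_haplo, as.integer(sire_idx), as.integer(dam_idx),
                     pos, length_cM, mutation_rate)
}

#' Population table
#'
#' Individual-level view of a `haplo_pop` as a tibble.
#'
#' @param pop A `haplo_pop`.
#' @return Tibble with `id`, `sire`, `dam`, `sex`, `generation`.
#' @export
pop_tibble <- function(pop) {
  tibble::tibble(id = pop$id, sire = pop$sire, dam = pop$dam,
                 sex = pop$sex, generation = pop$generation)
}
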