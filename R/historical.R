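#' Historical population size schedule
#'
#' Census-size trajectory of the historical (pre-breeding) population: a
#' constant founder phase at mutation-drift equilibrium, linear growth to a
#' peak, then a sharp decline (bottleneck) that builds linkage
#' disequilibrium. Defaults follow the standard cattle-like setting: 1000
#' founders held for 1000 generations, growth to 10,000 over the next 1000
#' generations, decline to 4,000 by generation 2020. The `scale` multiplier
#' shrinks all sizes *and* phase lengths proportionally, which preserves the
#' drift time-scale t/N (and hence the allele-frequency spectrum and relative
#' LD build-up) in reduced-scale runs.
#'
#' @param scale Proportional shrink factor for sizes and phase lengths.
#' @param founder_size,peak_size,end_size Census anchors (at `scale = 1`).
#' @param n_constant,n_growth,n_decline Phase lengths in generations (at
#'   `scale = 1`).
#' @return Tibble with `generation` (0-based) and integer `size`, one row per
#'   generation; sizes are interpolated linearly and rounded to the nearest
#'   even integer (>= 2) so the sexes stay balanced.
#' @export
size_schedule <- function(scale = 1, founder_size = 1000, peak_size = 10000,
                          end_size = 4000, n_constant = 1000, n_growth = 1000,
                          n_decline = 20) {
  if (scale <= 0) abort("`scale` must be positive.", class = "matesim_config_error")
  g1 <- max(1L, as.integer(round(n_constant * scale)))
  g2 <- max(1L, as.integer(round(n_growth * scale)))
  g3 <- max(1L, as.integer(round(n_decline * scale)))
  anchors_g <- c(0L, g1, g1 + g2, g1 + g2 + g3)
  anchors_n <- pmax(2, c(founder_size, founder_size, peak_size, end_size) * scale)
  gen <- 0:(g1 + g2 + g3)
  size <- stats::approx(anchors_g, anchors_n, xout = gen)$y
  size <- pmax(2L, 2L * as.integer(round(size / 2)))
  tibble::tibble(generation = gen, size = size)
}

#' Simulate the historical population
#'
#' Forward-in-time neutral simulation by random union of gametes: each
#' generation, every offspring draws a random sire and a random dam (with
#' replacement) from the previous generation and receives one gamete from
#' each ([meiosis()] model). Founders are initialised with allele frequency
#' 0.5 at every locus; the schedule's constant phase then lets drift and
#' recurrent mutation shape the equilibrium spectrum, and the final decline
#' creates LD. Sexes are assigned in an even split each generation.
#'
#' @param map A `genome_map` (markers and QTL are simulated jointly).
#' @param schedule A [size_schedule()] tibble (`generation`, `size`).
#' @param mutation_rate Per-locus per-generation allele-flip rate.
#' @param keep_generations Optional generation indices whose populations are
#'   returned alongside the final one (for trajectory diagnostics).
#' @return The final-generation `haplo_pop`; if `keep_generations` is
#'   non-empty, attribute `snapshots` holds a named list of the requested
#'   intermediate populations.
#' @export
simulate_historical <- function(map, schedule, mutation_rate = 2.5e-5,
                                keep_generations = integer(0)) {
  stopifnot(is.data.frame(schedule), all(c("generation", "size") %in% names(schedule)))
  if (any(schedule$size < 2)) abort("Schedule sizes must be >= 2.", class = "matesim_config_error")
  if (is.unsorted(schedule$generation, strictly = TRUE))
    abort("Schedule generations must be strictly increasing.", class = "matesim_config_error")
  pos <- map$pos_cM
  len <- map_length(map)
  L <- length(pos)
  n0 <- schedule$size[1]
  haplo <- matrix(as.raw(rbinom(L * 2 * n0, 1, 0.5)), L, 2 * n0)
  sex <- sample(rep(c("M", "F"), length.out = n0))
  pop <- haplo_pop(haplo, sex, generation = schedule$generation[1])
  snapshots <- list()
  gens <- schedule$generation[-1]
  sizes <- schedule$size[-1]
  for (k in seq_along(gens)) {
    n <- sizes[k]
    males <- which(pop$sex == "M")
    females <- which(pop$sex == "F")
    if (!length(males) || !length(females))
      abort("A sex is absent; cannot reproduce.", class = "matesim_sim_error")
    sire <- sample(males, n, replace = TRUE)
    dam <- sample(females, n, replace = TRUE)
    child <- drop_offspring(pop$haplo, sire, dam, pos, len, mutation_rate)
    sex <- sample(rep(c("M", "F"), length.out = n))
    pop <- haplo_pop(child, sex, generation = gens[k])
    if (gens[k] %in% keep_generations)
      snapshots[[as.character(gens[k])]] <- pop
  }
  if (length(snapshots)) attr(pop, "snapshots") <- snapshots
  pop
}
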