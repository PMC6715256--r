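#' Probability that a singleton phase assignment is correct
#'
#' When a heterozygous singleton is assigned to the chromosome with the
#' larger estimated first coalescent time, the assignment is correct with
#' probability t_c / (t_c + t_c*), where t_c* is the first coalescent time of
#' the rejected chromosome: the mutation is uniformly likely anywhere along
#' either branch, so the longer branch carries it with proportionally higher
#' probability. At equality the probability drops to 0.5.
#'
#' @param t_c estimated first coalescent time of one chromosome.
#' @param t_c_star estimated first coalescent time of the other.
#' @return max(t_c, t_c*) / (t_c + t_c*), in `[0.5, 1]`. Vectorized.
#' @export
phase_confidence <- function(t_c, t_c_star) {
  if (any(t_c <= 0) || any(t_c_star <= 0)) {
    stop("coalescent times must be positive")
  }
  pmax(t_c, t_c_star) / (t_c + t_c_star)
}

# internal: dual-t_c phase decisions for chosen singleton sites.
# Builds the singleton-masked alignment once, measures both chromosomes'
# tracts at each focal position, and dates each side.
.phase_decisions <- function(hm, map, params, sites, tie_tol = 1e-3) {
  v <- hm$variants
  M <- nrow(hm$alleles)
  # mask all singleton columns for tract extraction
  masked <- hm
  keep <- !(v$k == 1L)
  masked$alleles <- masked$alleles[, keep, drop = FALSE]
  masked$positions <- masked$positions[keep]
  masked$variants <- v[keep, , drop = FALSE]
  if (is.na(masked$chrom_length_bp) && length(hm$positions)) {
    # keep the original assayed span as the truncation bound
    masked$chrom_length_bp <- max(hm$positions)
  }

  carrier <- vapply(sites, function(s) which(hm$alleles[, s] == 1L)[1],
                    integer(1))
  ind <- (carrier + 1L) %/% 2L
  rowA <- 2L * ind - 1L
  rowB <- 2L * ind
  pos <- hm$positions[sites]

  obs <- msh_at(masked, c(rowA, rowB), c(pos, pos))
  obs <- compose_chi(obs, map, params$mu)
  obs$k <- 1L
  obs$group <- seq_len(nrow(obs))
  est <- estimate_tc_batch(obs, params)

  ns <- length(sites)
  tcA <- est$t_c[seq_len(ns)]
  tcB <- est$t_c[ns + seq_len(ns)]
  lenA <- genetic_position(map, pos + obs$msh3_bp[seq_len(ns)]) -
    genetic_position(map, pos - obs$msh5_bp[seq_len(ns)])
  lenB <- genetic_position(map, pos + obs$msh3_bp[ns + seq_len(ns)]) -
    genetic_position(map, pos - obs$msh5_bp[ns + seq_len(ns)])

  tie <- abs(log10(tcA) - log10(tcB)) < tie_tol
  chooseA <- tcA >= tcB | tie  # ties resolve to the first chromosome
  tibble::tibble(
    individual = ind, site = sites, pos = pos,
    chosen_row = ifelse(chooseA, rowA, rowB),
    rejected_row = ifelse(chooseA, rowB, rowA),
    t_c = ifelse(chooseA, tcA, tcB),
    t_c_star = ifelse(chooseA, tcB, tcA),
    confidence = phase_confidence(tcA, tcB),
    msh_ratio = pmax(lenA, lenB) / pmin(lenA, lenB),
    tie = tie
  )
}

#' Phase one heterozygous singleton by relative t_c
#'
#' Considers both possible placements of a heterozygous singleton on an
#' individual's two chromosomes. All singleton columns are masked during
#' tract extraction, the first coalescent time of each chromosome at the
#' focal position is estimated, and the variant is assigned to the
#' chromosome with the larger estimate (the longer branch is
#' proportionally more likely to carry the mutation). Ties within the
#' optimizer tolerance go to the individual's first chromosome and are
#' flagged.
#'
#' @param hm a [haplotype_matrix()] with diploid rows.
#' @param individual individual index (1-based; rows 2i-1 and 2i).
#' @param site singleton site column index; the individual must be its
#'   heterozygous carrier.
#' @param map a [genetic_map()].
#' @param params a [tc_params()] list.
#' @return A list with `decision` (one-row tibble: chosen row, t_c of both
#'   placements, confidence, tract-length ratio, tie flag) and `matrix`
#'   (the updated [haplotype_matrix()]).
#' @export
phase_singleton <- function(hm, individual, site, map, params) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  vc <- variant_carriers(hm, site)
  if (vc$k != 1L) stop("site ", site, " is not a singleton")
  rows <- c(2L * individual - 1L, 2L * individual)
  if (sum(hm$alleles[rows, site]) != 1L) {
    stop("individual ", individual, " is not a heterozygous carrier at site ",
         site)
  }
  dec <- .phase_decisions(hm, map, params, site)
  hm$alleles[rows, site] <- 0L
  hm$alleles[dec$chosen_row, site] <- 1L
  list(decision = dec, matrix = hm)
}

#' Phase all heterozygous singletons by relative t_c
#'
#' Applies the dual-t_c rule to every singleton in the matrix. All singleton
#' columns are masked first and each decision is made independently against
#' the masked alignment, then the assignments are committed together, so the
#' result does not depend on processing order.
#'
#' @inheritParams phase_singleton
#' @param sites singleton site columns to phase (default: all).
#' @return A list with `decisions` (tibble, one row per phased singleton)
#'   and `matrix` (the updated [haplotype_matrix()]).
#' @export
phase_singletons <- function(hm, map, params, sites = NULL) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  v <- hm$variants
  if (is.null(sites)) sites <- v$site[v$k == 1L & !v$masked]
  if (!length(sites)) {
    return(list(decisions = tibble::tibble(), matrix = hm))
  }
  dec <- .phase_decisions(hm, map, params, sites)
  for (i in seq_len(nrow(dec))) {
    rows <- c(dec$chosen_row[i], dec$rejected_row[i])
    hm$alleles[rows, dec$site[i]] <- c(1L, 0L)
  }
  list(decisions = dec, matrix = hm)
}

#' Randomly scramble the phase of heterozygous singletons
#'
#' Simulates the loss of singleton phase information in a genotype pipeline:
#' for every heterozygous singleton the allele is assigned to one of the
#' individual's two chromosomes uniformly at random. Used to evaluate
#' [phase_singletons()] against known truth.
#'
#' @param hm a [haplotype_matrix()] with diploid rows.
#' @param seed integer seed for reproducibility.
#' @return The scrambled [haplotype_matrix()].
#' @export
scramble_singleton_phase <- function(hm, seed = NULL) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  v <- hm$variants
  for (s in v$site[v$k == 1L]) {
    r <- which(hm$alleles[, s] == 1L)
    ind <- (r + 1L) %/% 2L
    rows <- c(2L * ind - 1L, 2L * ind)
    pick <- sample(rows, 1L)
    hm$alleles[rows, s] <- 0L
    hm$alleles[pick, s] <- 1L
  }
  hm
}
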