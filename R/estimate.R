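#' Estimate first coalescent times for the variants of a haplotype matrix
#'
#' End-to-end estimation: extracts per-copy maximum-shared-haplotype tracts
#' with the PBWT, composes the event statistic chi against the genetic map,
#' and maximizes the coalescent likelihood. With `mode = "pooled"` the k
#' copies of an allele are combined into one composite estimate per variant;
#' with `mode = "per_copy"` every copy is dated separately against its own
#' tract pair.
#'
#' @param hm a [haplotype_matrix()].
#' @param map a [genetic_map()].
#' @param params a [tc_params()] list; `n` defaults to the number of
#'   chromosome rows when the list was built without one.
#' @param mode `"pooled"` (one estimate per variant) or `"per_copy"`.
#' @param sites site column indices to estimate (default: all unmasked
#'   polymorphic sites).
#' @param singletons_only restrict to singleton variants.
#' @return A tibble with one row per estimate: `site`, `pos`, `k`, `copy`
#'   and `row` (per-copy mode), tract lengths and truncation flags, `chi`,
#'   `t_c` (generations), `loglik`, `boundary` and `low_information` flags.
#' @export
estimate_tc_variants <- function(hm, map, params, mode = c("pooled", "per_copy"),
                                 sites = NULL, singletons_only = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(hm, "haplotype_matrix"), inherits(map, "genetic_map"))
  obs <- msh_table(hm, sites = sites, singletons_only = singletons_only)
  if (!nrow(obs)) return(tibble::tibble())
  obs <- compose_chi(obs, map, params$mu)
  obs$group <- if (mode == "pooled") obs$site else seq_len(nrow(obs))
  est <- estimate_tc_batch(obs, params)
  if (mode == "pooled") {
    per_site <- obs |>
      dplyr::group_by(.data$site) |>
      dplyr::summarise(
        pos = .data$pos[1], k = .data$k[1],
        msh5_bp = mean(.data$msh5_bp), msh3_bp = mean(.data$msh3_bp),
        n_eoc = sum(.data$eoc5) + sum(.data$eoc3),
        .groups = "drop"
      )
    dplyr::left_join(per_site,
                     dplyr::select(est, group, t_c, loglik, boundary,
                                   low_information),
                     by = c(site = "group"))
  } else {
    obs$t_c <- est$t_c
    obs$loglik <- est$loglik
    obs$boundary <- est$boundary
    obs$low_information <- est$low_information
    dplyr::select(obs, site, pos, k, copy, row, msh5_bp, msh3_bp,
                  eoc5, eoc3, chi, beta, kernel, t_c, loglik,
                  boundary, low_information)
  }
}

#' Run the full estimator on a phased VCF
#'
#' Reads a phased VCF, optionally masks CpG transitions and rephases
#' singletons, and writes/returns the per-variant table of first coalescent
#' time estimates. This is the programmatic core of the command-line
#' interface.
#'
#' @param vcf path to a phased VCF.
#' @param map a [genetic_map()], or `NULL` to use a uniform map with rate
#'   `rho`.
#' @param mu per-base per-generation mutation rate.
#' @param rho uniform per-base recombination rate (used when `map` is NULL).
#' @param N0 constant diploid effective size for the sister-branch prior.
#' @param n sample size; defaults to the number of chromosomes in the VCF.
#' @param chrom chromosome to read (required for multi-chromosome files).
#' @param mode `"pooled"` or `"per_copy"` (see [estimate_tc_variants()]).
#' @param singletons_only estimate singletons only.
#' @param rephase_singletons phase heterozygous singletons by relative t_c
#'   before estimation (see [phase_singletons()]).
#' @param cpg_context reference context for CpG-transition masking, or
#'   `NULL` to skip masking (see [mask_cpg_transitions()]).
#' @param out optional output path; the table is written as tab-separated
#'   text with a commented header naming the units.
#' @return The estimates tibble, invisibly when `out` is given.
#' @export
run_tc <- function(vcf, map = NULL, mu = 1e-8, rho = 1e-8, N0 = 1e4,
                   n = NULL, chrom = NULL, mode = c("pooled", "per_copy"),
                   singletons_only = FALSE, rephase_singletons = FALSE,
                   cpg_context = NULL, out = NULL) {
  mode <- match.arg(mode)
  hm <- read_haplotypes(vcf, chrom = chrom)
  if (!is.null(cpg_context)) {
    hm <- mask_cpg_transitions(hm, cpg_context, action = "drop")
  }
  if (is.null(map)) map <- genetic_map(rate = rho)
  if (is.null(n)) n <- nrow(hm$alleles)
  params <- tc_params(mu = mu, n = n, demography = demography_constant(N0))
  if (rephase_singletons) {
    ph <- phase_singletons(hm, map, params)
    hm <- ph$matrix
  }
  res <- estimate_tc_variants(hm, map, params, mode = mode,
                              singletons_only = singletons_only)
  res <- tibble::tibble(chrom = hm$chrom,
                        ref = hm$variants$ref[match(res$site, hm$variants$site)],
                        alt = hm$variants$alt[match(res$site, hm$variants$site)],
                        res)
  if (rephase_singletons) attr(res, "phase_decisions") <- ph$decisions
  if (!is.null(out)) {
    con <- file(out, "w")
    on.exit(close(con))
    writeLines(c(
      "# first coalescent time estimates",
      "# t_c in generations; msh tract lengths in bp",
      paste0("# mu=", format(mu), " n=", n, " N0=", format(N0), " mode=", mode)
    ), con)
    utils::write.table(res, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(res))
  }
  res
}
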