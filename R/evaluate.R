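#' Score estimates against genealogical truth
#'
#' Computes the accuracy metrics used throughout the validation study — root
#' mean squared error, mean signed error (bias) and Pearson correlation of
#' log10-transformed first coalescent times — overall and stratified by
#' allele frequency (all variants, frequency <= 10%, <= 1%, singletons).
#'
#' @param estimates tibble of estimates. Per-copy estimates are joined to
#'   truth rows by `pos` and `row`; pooled per-variant estimates by `pos`
#'   alone (each copy then contributes one pair with its own truth).
#'   Alternatively pass a pre-joined tibble with columns `t_c`, `tc` and `k`
#'   and omit `truth`.
#' @param truth truth tibble from [simulate_sample()] (columns `pos`, `row`,
#'   `k`, `tc`).
#' @param n_chrom sample size in chromosomes (for the frequency strata).
#' @param per `"variant"` (default): one estimate/truth pair per variant, the
#'   unit the composite estimator reports (at a variant's focal position the
#'   carriers form a clade of the marginal tree, so all copies share one
#'   truth); `"copy"`: one pair per variant copy (weights variants by their
#'   allele count).
#' @return An object of class `tc_performance`: a tibble with one row per
#'   stratum (`stratum`, `n`, `rmse`, `bias`, `r`) carrying the paired data
#'   as an attribute. RMSE and bias are in log10 generations.
#' @export
evaluate_estimates <- function(estimates, truth = NULL, n_chrom,
                               per = c("variant", "copy")) {
  per <- match.arg(per)
  if (is.null(truth)) {
    pairs <- estimates
  } else {
    by <- if ("row" %in% names(estimates)) c("pos", "row") else "pos"
    pairs <- dplyr::inner_join(
      dplyr::select(truth, dplyr::all_of(c("pos", "row", "k", "tc"))),
      dplyr::select(estimates, -dplyr::any_of(setdiff(
        c("k", "site", "copy"), by))),
      by = by
    )
  }
  if (!nrow(pairs)) stop("no matched estimate/truth pairs")
  pairs <- dplyr::filter(pairs, is.finite(.data$t_c), .data$t_c > 0,
                         is.finite(.data$tc), .data$tc > 0)
  if (per == "variant") {
    pairs <- pairs |>
      dplyr::group_by(.data$pos) |>
      dplyr::summarise(k = .data$k[1],
                       tc = 10^mean(log10(.data$tc)),
                       t_c = 10^mean(log10(.data$t_c)),
                       .groups = "drop")
  }
  e <- log10(pairs$t_c)
  t <- log10(pairs$tc)
  strata <- list(
    all = rep(TRUE, nrow(pairs)),
    `freq<=10%` = pairs$k <= 0.10 * n_chrom,
    `freq<=1%` = pairs$k <= 0.01 * n_chrom,
    singletons = pairs$k == 1L
  )
  res <- purrr::map_dfr(names(strata), function(s) {
    i <- strata[[s]]
    if (sum(i) < 2) {
      return(tibble::tibble(stratum = s, n = sum(i), rmse = NA_real_,
                            bias = NA_real_, r = NA_real_))
    }
    d <- e[i] - t[i]
    tibble::tibble(
      stratum = s, n = sum(i),
      rmse = sqrt(mean(d^2)),
      bias = mean(d),
      r = stats::cor(t[i], e[i])
    )
  })
  structure(res, class = c("tc_performance", class(res)), pairs = pairs,
            n_chrom = n_chrom)
}

#' Idealized frequency-based comparator
#'
#' The best possible estimator that sees only allele frequency assigns every
#' variant of frequency k the same value tau_k; the least-squares choice is
#' the arithmetic mean of the true log10 t_c values in that class. Within a
#' class it therefore explains none of the variation, which is the contrast
#' the shared-haplotype estimator is designed to win for rare alleles.
#'
#' @param truth truth tibble with columns `k` and `tc` (one row per variant
#'   copy; copies of one variant share `k` and contribute individually).
#' @return A tibble with one row per frequency class: `k`, `n`, `tau`
#'   (mean true log10 t_c) and `resid_var` (variance left unexplained).
#' @export
frequency_comparator <- function(truth) {
  stopifnot(all(c("k", "tc") %in% names(truth)))
  truth |>
    dplyr::filter(is.finite(.data$tc), .data$tc > 0) |>
    dplyr::group_by(k = .data$k) |>
    dplyr::summarise(
      n = dplyr::n(),
      tau = mean(log10(.data$tc)),
      resid_var = if (dplyr::n() > 1) stats::var(log10(.data$tc)) else 0,
      .groups = "drop"
    )
}

#' Within-frequency explanatory power of both estimators
#'
#' For each allele-frequency class, the squared correlation between true and
#' estimated log10 t_c for the shared-haplotype estimator, alongside the
#' frequency-based comparator's (identically zero within a class, since all
#' its estimates coincide).
#'
#' @param pairs paired tibble with `k`, `tc` (truth) and `t_c` (estimate),
#'   e.g. the `pairs` attribute of [evaluate_estimates()].
#' @return A tibble: `k`, `n`, `r2_msh`, `r2_freq`.
#' @export
r2_by_frequency <- function(pairs) {
  pairs |>
    dplyr::filter(is.finite(.data$t_c), .data$t_c > 0,
                  is.finite(.data$tc), .data$tc > 0) |>
    dplyr::group_by(k = .data$k) |>
    dplyr::summarise(
      n = dplyr::n(),
      r2_msh = if (dplyr::n() > 2 && stats::sd(log10(.data$tc)) > 0 &&
                     stats::sd(log10(.data$t_c)) > 0) {
        stats::cor(log10(.data$tc), log10(.data$t_c))^2
      } else NA_real_,
      r2_freq = 0,
      .groups = "drop"
    )
}

#' Run one simulation-validation scenario
#'
#' Simulates a sample, estimates t_c for every variant (copy), and scores
#' the estimates against the recorded genealogical truth. With
#' `phase = "scrambled"` the singleton phase is first randomized and then
#' re-inferred with [phase_singletons()], emulating a pipeline in which
#' singleton phase is unknown.
#'
#' @inheritParams simulate_sample
#' @param mode `"pooled"` (composite estimate per variant, the default and
#'   the tool's reporting unit) or `"per_copy"` (each copy dated from its own
#'   tracts).
#' @param phase `"known"` or `"scrambled"`.
#' @param per scoring unit passed to [evaluate_estimates()].
#' @param params optional [tc_params()]; defaults to mu, a constant `N0`
#'   prior and `n` from the scenario.
#' @return A list: `performance` ([evaluate_estimates()] result), `pairs`
#'   (joined estimate/truth tibble), `estimates`, `sim`, and
#'   `phase_decisions` when rephasing ran.
#' @export
run_validation <- function(demography = "constant", n = 100, L_bp = 2e6,
                           mu = 1e-8, rho = 1e-8, seed = 1, N0 = 1e4,
                           mode = c("pooled", "per_copy"),
                           phase = c("known", "scrambled"),
                           per = c("variant", "copy"),
                           params = NULL, python = "python") {
  per <- match.arg(per)
  mode <- match.arg(mode)
  phase <- match.arg(phase)
  sim <- simulate_sample(demography, n = n, L_bp = L_bp, mu = mu, rho = rho,
                         seed = seed, N0 = N0, python = python)
  map <- genetic_map(rate = rho)
  if (is.null(params)) params <- tc_params(mu = mu, n = n, demography = N0)
  hm <- sim$hm
  decisions <- NULL
  if (phase == "scrambled") {
    hm <- scramble_singleton_phase(hm, seed = seed + 1000L)
    ph <- phase_singletons(hm, map, params)
    hm <- ph$matrix
    decisions <- ph$decisions
  }
  est <- estimate_tc_variants(hm, map, params, mode = mode)
  perf <- evaluate_estimates(est, sim$truth, n_chrom = n, per = per)
  list(performance = perf, pairs = attr(perf, "pairs"), estimates = est,
       sim = sim, phase_decisions = decisions)
}

#' Singleton phasing accuracy by tract-length ratio
#'
#' Joins committed phase decisions to the true carrier rows and bins the
#' accuracy by the ratio of the longer to the shorter of the two candidate
#' tract lengths. Accuracy should rise with the ratio: dissimilar tracts
#' make the carrying chromosome obvious, near-equal tracts drive the
#' decision towards a coin flip.
#'
#' @param decisions tibble from [phase_singletons()].
#' @param truth truth tibble from [simulate_sample()] (singleton rows give
#'   the true carrier).
#' @param bins number of ratio bins (quantile-spaced).
#' @return A tibble: `bin`, `ratio_mid`, `n`, `accuracy`.
#' @export
phasing_accuracy_by_ratio <- function(decisions, truth, bins = 5) {
  tr <- dplyr::filter(truth, .data$k == 1L)
  d <- dplyr::inner_join(decisions,
                         dplyr::select(tr, pos, true_row = "row"),
                         by = "pos")
  d$correct <- d$chosen_row == d$true_row
  qs <- stats::quantile(d$msh_ratio, probs = seq(0, 1, length.out = bins + 1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  d$bin <- cut(d$msh_ratio, breaks = unique(qs), labels = FALSE,
               include.lowest = TRUE)
  d |>
    dplyr::group_by(bin = .data$bin) |>
    dplyr::summarise(
      ratio_mid = stats::median(.data$msh_ratio),
      n = dplyr::n(),
      accuracy = mean(.data$correct),
      .groups = "drop"
    )
}
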