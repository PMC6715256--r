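#' Demographic models for the sister-branch prior
#'
#' The likelihood marginalizes over the unobserved sister-branch length using
#' a coalescent prior that depends on the historical effective population
#' size N(t). `demography_constant()` gives the constant-size model with a
#' closed-form prior; `demography_piecewise()` supports piecewise-exponential
#' histories N(t) = N_i * exp(-r_i * (t - t_i)) on [t_i, t_{i+1}), evaluated
#' through the numeric prior [phi_density_numeric()].
#'
#' @param N0 diploid effective population size.
#' @param times segment start times (generations before sampling; first must
#'   be 0).
#' @param sizes diploid size at the (recent) start of each segment.
#' @param rates per-generation exponential decay rate of size within each
#'   segment looking back in time (0 = constant within the segment).
#' @return An object of class `demography`.
#' @examples
#' demography_constant(1e4)
#' # growth from 1e4 to 5e5 over the last 200 generations:
#' r <- log(5e5 / 1e4) / 200
#' demography_piecewise(times = c(0, 200), sizes = c(5e5, 1e4),
#'                      rates = c(r, 0))
#' @export
demography_constant <- function(N0) {
  stopifnot(N0 > 0)
  structure(list(mode = "constant", N0 = N0), class = "demography")
}

#' @rdname demography_constant
#' @export
demography_piecewise <- function(times, sizes, rates = rep(0, length(times))) {
  stopifnot(length(times) == length(sizes), length(rates) == length(times),
            times[1] == 0, all(diff(times) > 0), all(sizes > 0))
  structure(list(mode = "piecewise", times = as.numeric(times),
                 sizes = as.numeric(sizes), rates = as.numeric(rates),
                 N0 = sizes[1]),
            class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  if (x$mode == "constant") {
    cat(sprintf("<demography> constant N = %g\n", x$N0))
  } else {
    cat(sprintf("<demography> piecewise-exponential, %d segments, N(0) = %g\n",
                length(x$times), x$sizes[1]))
  }
  invisible(x)
}

# N(t): diploid size t generations before sampling
.dem_N <- function(dem, t) {
  if (dem$mode == "constant") return(rep(dem$N0, length(t)))
  i <- findInterval(t, dem$times)
  i[i < 1L] <- 1L
  dem$sizes[i] * exp(-dem$rates[i] * (t - dem$times[i]))
}

# coalescent intensity tau(t) = integral_0^t 1/(2 N(s)) ds (closed per segment)
.dem_tau <- function(dem, t) {
  if (dem$mode == "constant") return(t / (2 * dem$N0))
  seg_int <- function(N0, r, dt) {
    # integral_0^dt exp(r s) / (2 N0) ds
    ifelse(rep(r == 0, length(dt)), dt / (2 * N0), expm1(r * dt) / (2 * N0 * r))
  }
  nseg <- length(dem$times)
  ends <- c(dem$times[-1], Inf)
  full <- cumsum(vapply(seq_len(nseg), function(i) {
    if (is.finite(ends[i])) seg_int(dem$sizes[i], dem$rates[i],
                                    ends[i] - dem$times[i]) else 0
  }, numeric(1)))
  base <- c(0, full[-nseg])
  i <- findInterval(t, dem$times)
  i[i < 1L] <- 1L
  base[i] + seg_int(dem$sizes[i], dem$rates[i], t - dem$times[i])
}

#' Sister-branch length prior, constant population size
#'
#' Under a constant diploid size N, the sister-branch length phi of a focal
#' lineage whose first coalescence is at t_c has a uniform density
#' n / (4N + n t_c) on [0, t_c) plus a point mass 1 - n t_c / (4N + n t_c)
#' at phi = t_c (the single-sister case). Density times t_c plus the mass
#' equals 1.
#'
#' @param phi sister branch length (generations); density is 0 outside
#'   `[0, t_c]`.
#' @param t_c first coalescent time (generations).
#' @param n sample size (chromosomes).
#' @param N diploid effective size.
#' @return Density values (per generation), or the point mass.
#' @export
phi_density_constantN <- function(phi, t_c, n, N) {
  stopifnot(t_c > 0, n >= 2, N > 0)
  ifelse(phi >= 0 & phi < t_c, n / (4 * N + n * t_c), 0)
}

#' @rdname phi_density_constantN
#' @export
phi_point_mass_constantN <- function(t_c, n, N) {
  stopifnot(t_c >= 0, n >= 2, N > 0)
  1 - n * t_c / (4 * N + n * t_c)
}

#' Sister-branch length prior for an arbitrary demography
#'
#' Builds the prior from the coalescent hazard along the focal branch:
#' with n(t) ~ n / (1 + (n/2) tau(t)) branches ancestral to the sample at
#' time t and hazard lambda(phi) = n(t_c - phi) / (4 N(t_c - phi)), the
#' density is f(phi) = lambda(phi) exp(-int_0^phi lambda). The survivor mass
#' at phi = t_c covers the single-sister case. The cumulative hazard has the
#' closed form log((1 + (n/2) tau(t_c)) / (1 + (n/2) tau(t_c - phi))), so no
#' quadrature is needed; with a constant demography the result reduces
#' exactly to [phi_density_constantN()].
#'
#' @inheritParams phi_density_constantN
#' @param demography a [demography_constant()] or [demography_piecewise()].
#' @return Density values; `phi_point_mass_numeric()` gives the mass at
#'   `phi = t_c`.
#' @export
phi_density_numeric <- function(phi, t_c, n, demography) {
  stopifnot(inherits(demography, "demography"), t_c > 0, n >= 2)
  t <- t_c - phi
  Nt <- .dem_N(demography, t)
  if (any(Nt <= 0)) stop("non-positive N(t)")
  nt <- n / (1 + (n / 2) * .dem_tau(demography, t))
  lambda <- nt / (4 * Nt)
  surv <- (1 + (n / 2) * .dem_tau(demography, t)) /
    (1 + (n / 2) * .dem_tau(demography, t_c))
  ifelse(phi >= 0 & phi < t_c, lambda * surv, 0)
}

#' @rdname phi_density_numeric
#' @export
phi_point_mass_numeric <- function(t_c, n, demography) {
  stopifnot(inherits(demography, "demography"), t_c >= 0, n >= 2)
  1 / (1 + (n / 2) * .dem_tau(demography, t_c))
}

# ---- stable building blocks for the closed-form likelihood ----------------
# J_m(a) = integral_0^1 (1+v)^m exp(-a v) dv, a >= 0, m in {0, 1, 2}.
# K_j(a) = integral_0^1 v^j exp(-a v) dv; series for small a avoids the
# catastrophic cancellation in the textbook antiderivative.

.K0 <- function(a) ifelse(a < 1e-12, 1 - a / 2, -expm1(-a) / a)

.K1 <- function(a) {
  small <- a < 1e-2
  out <- numeric(length(a))
  if (any(small)) {
    s <- a[small]
    out[small] <- 1 / 2 - s / 3 + s^2 / 8 - s^3 / 30 + s^4 / 144
  }
  if (any(!small)) {
    s <- a[!small]
    out[!small] <- (1 - (1 + s) * exp(-s)) / s^2
  }
  out
}

.K2 <- function(a) {
  small <- a < 1e-2
  out <- numeric(length(a))
  if (any(small)) {
    s <- a[small]
    out[small] <- 1 / 3 - s / 4 + s^2 / 10 - s^3 / 36 + s^4 / 168
  }
  if (any(!small)) {
    s <- a[!small]
    out[!small] <- (2 - (2 + 2 * s + s^2) * exp(-s)) / s^3
  }
  out
}

.Jm <- function(a, m) {
  switch(as.character(m),
         "0" = .K0(a),
         "1" = .K0(a) + .K1(a),
         "2" = .K0(a) + 2 * .K1(a) + .K2(a),
         stop("kernel m must be 0, 1 or 2"))
}

.logsumexp2 <- function(l1, l2) {
  m <- pmax(l1, l2)
  m + log(exp(l1 - m) + exp(l2 - m))
}

#' Log-likelihood of an msh observation given t_c
#'
#' Evaluates log p(chi | t_c) for one observation class, marginalized over
#' the sister-branch length. For a constant demography the integral over the
#' uniform-plus-point-mass prior has a closed form: with a = chi * t_c,
#'
#'   p(chi | t_c) = n/(4N + n t_c) * coef * t_c^(m+1) * exp(-a) * J_m(a)
#'                + 4N/(4N + n t_c) * coef * (2 t_c)^m * exp(-2 a)
#'
#' where J_m(a) = int_0^1 (1+v)^m e^(-a v) dv, m is the event-kernel power
#' (2 = both tracts mismatch-terminated, coef = beta; 1 = one side truncated
#' at the region end, coef = beta_eoc; 0 = both sides truncated, coef = 1)
#' and the second term is the single-sister point mass. Everything is
#' computed in log space with series-protected J_m, so the result is stable
#' from chi * t_c near 0 up to extreme arguments. For a non-constant
#' demography the marginalization uses adaptive quadrature over
#' [phi_density_numeric()]; `method = "quadrature"` forces that path (it is
#' also the validation oracle for the closed form).
#'
#' @param chi composite event statistic (mutational + recombinational
#'   opportunity; >= 0). Vectorized.
#' @param beta product of per-base event rates at the tract terminators
#'   (coefficient of the kernel; use 1 for kernel 0). Vectorized.
#' @param t_c candidate first coalescent time (generations, > 0). Vectorized.
#' @param n sample size (chromosomes).
#' @param demography a [demography_constant()] or [demography_piecewise()];
#'   a plain number is shorthand for a constant size.
#' @param kernel event-kernel power: 2, 1 or 0 (may be a vector).
#' @param method `"closed"` (default; constant demography only) or
#'   `"quadrature"`.
#' @return log p(chi | t_c), same length as the inputs.
#' @export
loglik_msh <- function(chi, beta, t_c, n, demography, kernel = 2L,
                       method = c("closed", "quadrature")) {
  method <- match.arg(method)
  if (is.numeric(demography)) demography <- demography_constant(demography)
  if (any(t_c <= 0)) stop("t_c must be > 0")
  if (any(chi < 0)) stop("chi must be >= 0")
  ln <- max(length(chi), length(beta), length(t_c), length(kernel))
  chi <- rep_len(chi, ln); beta <- rep_len(beta, ln)
  t_c <- rep_len(t_c, ln); kernel <- rep_len(as.integer(kernel), ln)

  if (method == "quadrature" || demography$mode != "constant") {
    return(.loglik_msh_quad(chi, beta, t_c, n, demography, kernel))
  }
  N <- demography$N0
  a <- chi * t_c
  lJ <- numeric(ln)
  for (m in unique(kernel)) {
    i <- kernel == m
    lJ[i] <- log(.Jm(a[i], m))
  }
  l1 <- log(n) - log(4 * N + n * t_c) + log(beta) +
    (kernel + 1) * log(t_c) - a + lJ
  l2 <- log(4 * N) - log(4 * N + n * t_c) + log(beta) +
    kernel * log(2 * t_c) - 2 * a
  .logsumexp2(l1, l2)
}

.loglik_msh_quad <- function(chi, beta, t_c, n, demography, kernel) {
  vapply(seq_along(chi), function(i) {
    tc <- t_c[i]; x <- chi[i]; m <- kernel[i]
    # exp(-x * tc) factored out so the integrand cannot underflow
    f <- function(phi) {
      phi_density_numeric(phi, tc, n, demography) *
        (tc + phi)^m * exp(-x * phi)
    }
    int <- stats::integrate(f, 0, tc, rel.tol = 1e-10,
                            abs.tol = 0, stop.on.error = FALSE)$value
    mass <- phi_point_mass_numeric(tc, n, demography) *
      (2 * tc)^m * exp(-x * tc)
    log(beta[i]) + log(int + mass) - x * tc
  }, numeric(1))
}

#' Probability of at least one mutation on the focal branch
#'
#' A derived singleton allele requires one or more mutations on the focal
#' branch of length t_c; the probability is 1 - exp(-mu * t_c). Added (in
#' log space) to the likelihood when dating a derived singleton; omitted when
#' dating an arbitrary base.
#'
#' @param t_c first coalescent time (generations).
#' @param mu per-base per-generation mutation rate.
#' @param log return the log probability.
#' @return Probability (or log probability) of >= 1 mutation.
#' @export
singleton_mutation_factor <- function(t_c, mu, log = FALSE) {
  x <- -expm1(-mu * t_c)
  if (log) base::log(x) else x
}

#' Composite log-likelihood over the copies of an allele
#'
#' Sums the per-copy log-likelihoods of the k msh observations of an allele
#' at a common candidate t_c (the copies are treated as independent, giving
#' a composite likelihood). For a singleton (one observation with `k == 1`)
#' the mutation factor [singleton_mutation_factor()] is added once.
#'
#' @param observations tibble with columns `chi`, `beta`, `kernel` (see
#'   [compose_chi()]) and optionally `k`.
#' @param t_c candidate first coalescent time (scalar).
#' @param params list with `mu`, `n`, `demography` (see
#'   [tc_params()]).
#' @return The composite log-likelihood (scalar).
#' @export
composite_loglik <- function(observations, t_c, params) {
  if (!nrow(observations)) stop("no observations")
  ll <- sum(loglik_msh(observations$chi, observations$beta, t_c,
                       params$n, params$demography, observations$kernel,
                       method = params$method %||% "closed"))
  single <- !is.null(observations$k) && nrow(observations) == 1L &&
    !is.na(observations$k[1]) && observations$k[1] == 1L
  if (single && isTRUE(params$mutation_factor)) {
    ll <- ll + singleton_mutation_factor(t_c, params$mu, log = TRUE)
  }
  ll
}

#' Estimation parameters
#'
#' Bundles the estimator's tunable parameters. Defaults follow the human
#' autosome settings: mutation rate 1e-8 per bp per generation and a constant
#' diploid effective size of 1e4; the sample size n should be the number of
#' chromosomes in the panel.
#'
#' @param mu per-base per-generation mutation rate.
#' @param n sample size in chromosomes.
#' @param demography a demography object or a constant diploid size.
#' @param log10_bounds optimizer search bounds for log10(t_c), generations.
#' @param tol absolute optimizer tolerance on the log10 scale.
#' @param method likelihood evaluation path (`"closed"` or `"quadrature"`).
#' @param mutation_factor include the singleton mutation factor when dating
#'   derived singleton alleles.
#' @return A parameter list.
#' @export
tc_params <- function(mu = 1e-8, n, demography = demography_constant(1e4),
                      log10_bounds = c(0, 7), tol = 1e-4,
                      method = c("closed", "quadrature"),
                      mutation_factor = TRUE) {
  if (is.numeric(demography)) demography <- demography_constant(demography)
  stopifnot(mu > 0, n >= 2)
  list(mu = mu, n = n, demography = demography,
       log10_bounds = log10_bounds, tol = tol,
       method = match.arg(method), mutation_factor = mutation_factor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum-likelihood estimate of t_c for one allele
#'
#' Maximizes the composite log-likelihood of the allele's msh observations
#' over log10(t_c) by bounded one-dimensional (Brent-type) optimization. A
#' coarse grid pass brackets the maximum first, so a boundary optimum is
#' detected and flagged.
#'
#' @param observations per-copy msh observations with `chi`, `beta`,
#'   `kernel` columns (see [compose_chi()]).
#' @param params a [tc_params()] list.
#' @return An object of class `tc_estimate`: fields `t_c` (generations),
#'   `loglik`, `k`, `convergence`, `boundary`, `low_information` (all copies
#'   doubly truncated), `bounds`, and the observations used.
#' @export
estimate_tc <- function(observations, params) {
  if (!nrow(observations)) stop("no observations")
  f <- function(l) composite_loglik(observations, 10^l, params)
  b <- params$log10_bounds
  grid <- seq(b[1], b[2], length.out = 61)
  fg <- vapply(grid, f, numeric(1))
  if (all(!is.finite(fg))) {
    return(.tc_estimate(NA_real_, NA_real_, observations, params,
                        convergence = FALSE, boundary = FALSE))
  }
  i <- which.max(fg)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = params$tol)
  l_hat <- opt$maximum
  ll <- opt$objective
  if (fg[i] > ll) { l_hat <- grid[i]; ll <- fg[i] }
  boundary <- l_hat <= b[1] + 2 * params$tol || l_hat >= b[2] - 2 * params$tol
  .tc_estimate(10^l_hat, ll, observations, params,
               convergence = is.finite(ll), boundary = boundary)
}

.tc_estimate <- function(t_c, loglik, observations, params,
                         convergence, boundary) {
  structure(
    list(t_c = t_c, loglik = loglik,
         k = nrow(observations),
         chi = observations$chi,
         convergence = convergence, boundary = boundary,
         low_information = all(observations$kernel == 0L),
         bounds = 10^params$log10_bounds, params = params,
         observations = observations),
    class = "tc_estimate"
  )
}

#' @export
print.tc_estimate <- function(x, ...) {
  cat(sprintf(
    "<tc_estimate> t_c = %.4g generations (logL %.4g, %d cop%s)%s%s\n",
    x$t_c, x$loglik, x$k, if (x$k == 1) "y" else "ies",
    if (x$boundary) " [boundary]" else "",
    if (x$low_information) " [low information]" else ""
  ))
  invisible(x)
}

#' Batch maximum-likelihood estimation of t_c
#'
#' Vectorized estimation across many alleles or copies: a shared coarse grid
#' over log10(t_c) brackets each group's maximum, then golden-section
#' iterations (vectorized across groups) refine it to the optimizer
#' tolerance. Results match [estimate_tc()] applied group by group.
#'
#' @param observations tibble with `chi`, `beta`, `kernel`, `k` and a `group`
#'   column identifying which rows are pooled into one composite estimate
#'   (one group per allele for pooled estimation, one per copy for per-copy
#'   estimation).
#' @param params a [tc_params()] list.
#' @return A tibble with one row per group: `group`, `t_c`, `loglik`, `k`,
#'   `boundary`, `low_information`.
#' @export
estimate_tc_batch <- function(observations, params) {
  stopifnot(nrow(observations) > 0, !is.null(observations$group))
  g <- as.integer(factor(observations$group,
                         levels = unique(observations$group)))
  ng <- max(g)
  chi <- observations$chi; beta <- observations$beta
  kern <- as.integer(observations$kernel)
  # mutation factor applies once per group when the allele is a singleton
  singles <- rep(FALSE, ng)
  if (isTRUE(params$mutation_factor) && !is.null(observations$k)) {
    tab <- tabulate(g, ng)
    kk <- rep(NA_integer_, ng)
    kk[g] <- observations$k
    singles <- tab == 1L & !is.na(kk) & kk == 1L
  }
  obj <- function(lvec) {  # lvec: per-group log10 t_c
    tc_row <- 10^lvec[g]
    ll <- loglik_msh(chi, beta, tc_row, params$n, params$demography, kern,
                     method = params$method %||% "closed")
    tot <- as.numeric(rowsum(ll, g, reorder = TRUE))
    ms <- singles
    tot[ms] <- tot[ms] +
      singleton_mutation_factor(10^lvec[ms], params$mu, log = TRUE)
    tot
  }
  b <- params$log10_bounds
  grid <- seq(b[1], b[2], length.out = 61)
  best <- rep(-Inf, ng); besti <- rep(1L, ng)
  for (j in seq_along(grid)) {
    fj <- obj(rep(grid[j], ng))
    upd <- fj > best
    best[upd] <- fj[upd]; besti[upd] <- j
  }
  step <- grid[2] - grid[1]
  lo <- pmax(b[1], grid[besti] - step)
  hi <- pmin(b[2], grid[besti] + step)
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- obj(x1); f2 <- obj(x2)
  iters <- ceiling(log(params$tol / (2 * step)) / log(gr))
  for (it in seq_len(max(iters, 1))) {
    left <- f1 > f2
    hi[left] <- x2[left]
    x2[left] <- x1[left]; f2[left] <- f1[left]
    x1[left] <- hi[left] - gr * (hi[left] - lo[left])
    lo[!left] <- x1[!left]
    x1[!left] <- x2[!left]; f1[!left] <- f2[!left]
    x2[!left] <- lo[!left] + gr * (hi[!left] - lo[!left])
    fn <- obj(ifelse(left, x1, x2))
    f1[left] <- fn[left]; f2[!left] <- fn[!left]
  }
  l_hat <- (lo + hi) / 2
  ll <- obj(l_hat)
  kg <- rep(NA_integer_, ng); kg[g] <- observations$k %||% NA_integer_
  li <- as.numeric(rowsum(as.numeric(kern == 0L), g)) ==
    as.numeric(rowsum(rep(1, length(g)), g))
  tibble::tibble(
    group = unique(observations$group),
    t_c = 10^l_hat, loglik = ll, k = kg,
    boundary = l_hat <= b[1] + 10 * params$tol | l_hat >= b[2] - 10 * params$tol,
    low_information = li
  )
}
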