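#' Build positional Burrows-Wheeler prefix and divergence arrays
#'
#' Runs Durbin's PBWT update over the haplotype alignment and returns the
#' full prefix-order (`a`) and divergence (`d`) arrays. Column `t` of each
#' array describes the state before incorporating site `t`, i.e. the ordering
#' of chromosomes by reversed prefix over sites `1..t-1`; there are
#' `n_sites + 1` columns. `a[i, t]` is the chromosome row at rank `i`;
#' `d[i, t]` is the first site of the match between the chromosomes at ranks
#' `i - 1` and `i` (`d[1, t] = t`, the empty match: consecutive chromosomes
#' in `a`-order agree on sites `d[i, t] .. t - 1`).
#'
#' @param x a [haplotype_matrix()] or a binary 0/1 matrix (rows =
#'   chromosomes).
#' @param reverse build on reversed site order (used for 3' tracts); indices
#'   in the result then refer to the reversed alignment.
#' @return A list with integer matrices `a` and `d` (both 1-based).
#' @references Durbin R (2014) Efficient haplotype matching and storage using
#'   the positional Burrows-Wheeler transform. Bioinformatics 30:1266-1272.
#' @export
build_pbwt <- function(x, reverse = FALSE) {
  X <- if (inherits(x, "haplotype_matrix")) x$alleles else x
  storage.mode(X) <- "integer"
  if (reverse) X <- X[, rev(seq_len(ncol(X))), drop = FALSE]
  res <- .pbwt_build_cpp(X)
  list(a = res$a + 1L, d = res$d + 1L)
}

# Internal: streamed msh queries in one orientation.
# qcol0: 0-based insertion column; qrow0: 0-based focal rows; excl0: list of
# 0-based rows to skip. Returns 0-based match start and 0-based partner.
.msh_query_raw <- function(X, qcol0, qrow0, excl0) {
  storage.mode(X) <- "integer"
  .pbwt_msh_query_cpp(X, as.integer(qcol0), as.integer(qrow0), excl0)
}

# Internal: both-direction msh for (row, position[, site]) queries.
# exclude: list of 1-based row vectors (match partners never considered).
.msh_points <- function(hm, rows, positions, exclude = NULL) {
  X <- hm$alleles
  S <- ncol(X)
  pos <- hm$positions
  nq <- length(rows)
  if (is.null(exclude)) exclude <- rep(list(integer(0)), nq)
  excl0 <- lapply(exclude, function(e) as.integer(e) - 1L)
  bounds <- .chrom_bounds(hm)

  c_fwd0 <- findInterval(positions - 0.5, pos)      # cols with pos < p
  c_rev0 <- S - findInterval(positions + 0.5, pos)  # cols with pos > p
  fw <- .msh_query_raw(X, c_fwd0, rows - 1L, excl0)
  Xr <- X[, rev(seq_len(S)), drop = FALSE]
  rv <- .msh_query_raw(Xr, c_rev0, rows - 1L, excl0)
  if (anyNA(fw$start) || anyNA(rv$start)) {
    stop("no eligible match partner (all other chromosomes excluded)")
  }

  ter5_col <- fw$start                         # 1-based terminator column
  eoc5 <- ter5_col == 0L
  ter5_pos <- ifelse(eoc5, NA_real_, pos[pmax(ter5_col, 1L)])
  msh5 <- ifelse(eoc5, positions - bounds[1], positions - ter5_pos)

  ter3_col <- ifelse(rv$start == 0L, 0L, S - rv$start + 1L)
  eoc3 <- rv$start == 0L
  ter3_pos <- ifelse(eoc3, NA_real_, pos[pmax(ter3_col, 1L)])
  msh3 <- ifelse(eoc3, bounds[2] - positions, ter3_pos - positions)

  tibble::tibble(
    row = rows, pos = positions,
    msh5_bp = as.numeric(msh5), msh3_bp = as.numeric(msh3),
    eoc5 = eoc5, eoc3 = eoc3,
    ter5_pos = as.numeric(ter5_pos), ter3_pos = as.numeric(ter3_pos),
    partner5 = fw$partner + 1L, partner3 = rv$partner + 1L
  )
}

#' Maximum shared haplotype of a singleton variant
#'
#' For the single carrier of a derived singleton allele, measures the longest
#' tract of sequence identity between the carrier chromosome and any other
#' chromosome, separately in the 5' and 3' directions. The focal column
#' itself is ignored in the comparison (it mismatches every non-carrier by
#' construction: the variant being dated is not a terminator). The two
#' directions may be realized against different chromosomes.
#'
#' @param hm a [haplotype_matrix()].
#' @param site site column index of the singleton.
#' @return A one-row msh tibble (see [msh_table()] for the columns).
#' @export
msh_singleton <- function(hm, site) {
  vc <- variant_carriers(hm, site)
  if (vc$k != 1L) stop("site ", site, " is not a singleton (k = ", vc$k, ")")
  out <- .msh_points(hm, vc$carriers, hm$positions[site],
                     exclude = list(integer(0)))
  tibble::tibble(site = site, k = 1L, copy = 1L, out)
}

#' Maximum shared haplotypes of a multi-copy variant
#'
#' For each of the k carriers of a derived allele, measures the longest
#' identity tract between that carrier and any chromosome *not* carrying the
#' allele, per direction (each direction maximized independently).
#'
#' @inheritParams msh_singleton
#' @param site site column index with 2 <= k <= rows - 1.
#' @return An msh tibble with one row per carrier copy.
#' @export
msh_multicopy <- function(hm, site) {
  vc <- variant_carriers(hm, site)
  if (vc$k < 2L) stop("site ", site, " has k < 2; use msh_singleton()")
  if (vc$k >= nrow(hm$alleles)) stop("no non-carrier chromosome exists")
  out <- .msh_points(hm, vc$carriers,
                     rep(hm$positions[site], vc$k),
                     exclude = rep(list(vc$carriers), vc$k))
  tibble::tibble(site = site, k = vc$k, copy = seq_len(vc$k), out)
}

#' msh tracts for every variant copy
#'
#' Streams the PBWT once in each direction and extracts per-copy 5' and 3'
#' maximum-shared-haplotype tracts for all (or selected) polymorphic,
#' unmasked sites. For singletons the comparison panel is every other
#' chromosome; for k-copy variants it is the non-carriers.
#'
#' @param hm a [haplotype_matrix()].
#' @param sites site column indices (default: all unmasked polymorphic sites).
#' @param singletons_only restrict to k = 1 sites.
#' @return A tibble with one row per variant copy: `site`, `pos`, `k`,
#'   `copy`, focal `row`, tract lengths `msh5_bp`/`msh3_bp` (bp from the
#'   focal base to the first non-identical site, or to the region bound),
#'   truncation flags `eoc5`/`eoc3`, terminator positions
#'   `ter5_pos`/`ter3_pos` (NA when truncated) and best-match partners.
#' @export
msh_table <- function(hm, sites = NULL, singletons_only = FALSE) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  v <- hm$variants
  M <- nrow(hm$alleles)
  if (is.null(sites)) {
    sites <- v$site[!v$masked & v$k >= 1L & v$k <= M - 1L]
  }
  if (singletons_only) sites <- sites[v$k[sites] == 1L]
  if (!length(sites)) {
    return(tibble::tibble(
      site = integer(), pos = numeric(), k = integer(), copy = integer(),
      row = integer(), msh5_bp = numeric(), msh3_bp = numeric(),
      eoc5 = logical(), eoc3 = logical(), ter5_pos = numeric(),
      ter3_pos = numeric(), partner5 = integer(), partner3 = integer()
    ))
  }
  carriers <- lapply(sites, function(s) which(hm$alleles[, s] == 1L))
  k <- lengths(carriers)
  rows <- unlist(carriers)
  site_rep <- rep(sites, k)
  excl <- rep(lapply(carriers, as.integer), k)
  out <- .msh_points(hm, rows, hm$positions[site_rep], exclude = excl)
  copy <- unlist(lapply(k, seq_len))
  tibble::tibble(site = site_rep, k = rep(as.integer(k), k), copy = copy, out)
}

#' msh tracts at arbitrary positions
#'
#' Measures per-direction maximum-shared-haplotype tracts for given
#' (chromosome row, physical position) pairs against the whole panel. Used by
#' singleton phasing, where the focal position's column has been masked out
#' of the alignment.
#'
#' @param hm a [haplotype_matrix()].
#' @param rows focal chromosome rows (vectorized).
#' @param positions focal physical positions (same length).
#' @return An msh tibble (see [msh_table()]).
#' @export
msh_at <- function(hm, rows, positions) {
  stopifnot(inherits(hm, "haplotype_matrix"), length(rows) == length(positions))
  .msh_points(hm, as.integer(rows), as.numeric(positions))
}

#' Brute-force msh oracle
#'
#' Direct O(rows x sites) scan of identity tracts around a focal site,
#' maximized over the allowed chromosomes. Independent of the PBWT code path;
#' used to validate it.
#'
#' @param hm a [haplotype_matrix()].
#' @param row focal chromosome row.
#' @param site focal site column (the column itself is ignored in
#'   comparisons).
#' @param exclude_rows rows never considered as match partners.
#' @return A one-row msh tibble (see [msh_table()]).
#' @export
brute_force_msh <- function(hm, row, site, exclude_rows = integer(0)) {
  X <- hm$alleles
  S <- ncol(X)
  pos <- hm$positions
  bounds <- .chrom_bounds(hm)
  others <- setdiff(seq_len(nrow(X)), c(row, exclude_rows))
  if (!length(others)) stop("no eligible match partner")
  p <- pos[site]

  best5_col <- Inf; best5_row <- NA_integer_  # want smallest mismatch col
  best3_col <- -Inf; best3_row <- NA_integer_
  # per direction: longest tract = mismatch farthest from the focal site
  m5 <- S + 1L; m3 <- 0L
  for (o in others) {
    mism <- which(X[row, ] != X[o, ])
    mism <- mism[mism != site]
    left <- mism[mism < site]
    right <- mism[mism > site]
    l <- if (length(left)) max(left) else 0L    # 0 = reaches start
    r <- if (length(right)) min(right) else S + 1L
    if (l < m5 || (l == m5 && o < best5_row)) { m5 <- l; best5_row <- o }
    if (r > m3 || (r == m3 && o < best3_row)) { m3 <- r; best3_row <- o }
  }
  eoc5 <- m5 == 0L
  eoc3 <- m3 == S + 1L
  ter5 <- if (eoc5) NA_real_ else pos[m5]
  ter3 <- if (eoc3) NA_real_ else pos[m3]
  msh5 <- if (eoc5) p - bounds[1] else p - ter5
  msh3 <- if (eoc3) bounds[2] - p else ter3 - p
  tibble::tibble(
    site = site, k = NA_integer_, copy = NA_integer_,
    row = row, pos = p,
    msh5_bp = msh5, msh3_bp = msh3,
    eoc5 = eoc5, eoc3 = eoc3,
    ter5_pos = ter5, ter3_pos = ter3,
    partner5 = best5_row, partner3 = best3_row
  )
}
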