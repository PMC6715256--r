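#' Construct a genetic map
#'
#' A genetic map is a monotone piecewise-linear function from physical
#' position (bp) to cumulative genetic position (Morgans). Between anchors the
#' map is linear; beyond the terminal anchors the nearest interval's rate is
#' extrapolated at a constant per-base rate. A uniform map (constant rate
#' everywhere) can be built from a single per-base rate.
#'
#' @param bp anchor physical positions (bp, strictly increasing; >= 2 anchors).
#' @param morgans cumulative genetic position at each anchor (Morgans,
#'   non-decreasing).
#' @param rate uniform per-base recombination rate (Morgans/bp); give this
#'   instead of `bp`/`morgans` for a uniform map.
#' @return An object of class `genetic_map`.
#' @examples
#' genetic_map(rate = 1e-8)                       # uniform 1 cM/Mb
#' genetic_map(bp = c(1, 1e6 + 1), morgans = c(0, 0.01))
#' @export
genetic_map <- function(bp = NULL, morgans = NULL, rate = NULL) {
  if (!is.null(rate)) {
    if (rate < 0) stop("rate must be >= 0")
    return(structure(list(uniform_rate = rate, bp = NULL, morgans = NULL),
                     class = "genetic_map"))
  }
  if (length(bp) < 2) stop("a tabulated genetic map needs at least 2 anchors")
  if (any(diff(bp) <= 0)) stop("anchor positions must be strictly increasing")
  if (any(diff(morgans) < 0)) stop("cumulative Morgans must be non-decreasing")
  structure(list(uniform_rate = NULL, bp = as.numeric(bp),
                 morgans = as.numeric(morgans),
                 slopes = diff(morgans) / diff(bp)),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  if (!is.null(x$uniform_rate)) {
    cat(sprintf("<genetic_map> uniform, %.3g Morgans/bp (%.3g cM/Mb)\n",
                x$uniform_rate, x$uniform_rate * 1e8))
  } else {
    cat(sprintf("<genetic_map> %d anchors, %s-%s bp, %.4g cM total\n",
                length(x$bp), format(min(x$bp)), format(max(x$bp)),
                100 * (max(x$morgans) - min(x$morgans))))
  }
  invisible(x)
}

#' Read a genetic map file
#'
#' Accepts the common tab/space-delimited dialects with an auto-detected
#' header line: 4 columns (chrom, bp, rate cM/Mb, cumulative cM), 3 columns
#' (bp, rate cM/Mb, cumulative cM), or 2 columns (bp, cumulative cM).
#' Centimorgans are converted to Morgans internally.
#'
#' @param path map file path.
#' @param chrom restrict a 4-column file to one chromosome.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path, chrom = NULL) {
  first <- readLines(path, n = 1L)
  toks <- strsplit(trimws(first), "[ \t]+")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(toks[-1])))
  df <- utils::read.table(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 4) {
    if (!is.null(chrom)) df <- df[as.character(df[[1]]) == as.character(chrom), ]
    if (nrow(df) == 0) stop("no map rows for chromosome ", chrom)
    bp <- df[[2]]; cm <- df[[4]]
  } else if (ncol(df) == 3) {
    bp <- df[[1]]; cm <- df[[3]]
  } else if (ncol(df) == 2) {
    bp <- df[[1]]; cm <- df[[2]]
  } else {
    stop("unrecognized genetic map layout (", ncol(df), " columns)")
  }
  o <- order(bp)
  genetic_map(bp = bp[o], morgans = cm[o] / 100)
}

#' Genetic position of physical coordinates
#'
#' Piecewise-linear interpolation between map anchors, with constant-rate
#' extrapolation of the terminal intervals beyond the map ends.
#'
#' @param map a [genetic_map()].
#' @param bp physical positions (vectorized).
#' @return Cumulative genetic positions in Morgans.
#' @export
genetic_position <- function(map, bp) {
  stopifnot(inherits(map, "genetic_map"))
  if (!is.null(map$uniform_rate)) return(map$uniform_rate * bp)
  n <- length(map$bp)
  out <- stats::approx(map$bp, map$morgans, xout = bp, rule = 2)$y
  below <- bp < map$bp[1]
  above <- bp > map$bp[n]
  if (any(below)) {
    out[below] <- map$morgans[1] - (map$bp[1] - bp[below]) * map$slopes[1]
  }
  if (any(above)) {
    out[above] <- map$morgans[n] + (bp[above] - map$bp[n]) * map$slopes[n - 1]
  }
  out
}

#' Local per-base recombination rate
#'
#' The slope (Morgans/bp) of the map interval containing each position.
#' A query exactly at an interior anchor takes the right-hand interval's
#' slope; queries beyond the map ends take the terminal interval's slope.
#'
#' @inheritParams genetic_position
#' @return Per-base rates (Morgans/bp).
#' @export
local_rho <- function(map, bp) {
  stopifnot(inherits(map, "genetic_map"))
  if (!is.null(map$uniform_rate)) return(rep(map$uniform_rate, length(bp)))
  n <- length(map$bp)
  # interval i covers [bp_i, bp_{i+1}); right-interval slope at anchors
  idx <- findInterval(bp, map$bp)
  idx[idx < 1L] <- 1L
  idx[idx > n - 1L] <- n - 1L
  map$slopes[idx]
}

#' Compose the per-branch event statistic chi from msh observations
#'
#' Converts per-copy 5' and 3' maximum-shared-haplotype tracts into the
#' composite event statistic used by the likelihood: chi combines the
#' mutational opportunity (mu times the summed tract lengths in bp) with the
#' recombinational opportunity (the tract lengths in Morgans), and beta is
#' the product of per-base total event rates at the tract terminators.
#'
#' Three observation types arise: both tracts terminated by a mismatch
#' (`kernel = 2`, `chi = mu*(msh5+msh3) + c5 + c3`,
#' `beta = (mu+rho5)*(mu+rho3)`); one side truncated at the end of the
#' assayed region (`kernel = 1`, `chi = mu*(msh+msh_eoc) + c + c_eoc`,
#' `beta = mu + rho` at the complete side's terminator); and both sides
#' truncated (`kernel = 0`, a pure no-event observation with `beta = 1`,
#' flagged low-information).
#'
#' @param msh_obs tibble of msh observations as returned by [msh_table()]
#'   (columns `pos`, `msh5_bp`, `msh3_bp`, `eoc5`, `eoc3`, `ter5_pos`,
#'   `ter3_pos`).
#' @param map a [genetic_map()].
#' @param mu per-base per-generation mutation rate.
#' @return The input tibble with columns `chi`, `beta` and `kernel` added.
#' @export
compose_chi <- function(msh_obs, map, mu) {
  stopifnot(is.data.frame(msh_obs), inherits(map, "genetic_map"), mu > 0)
  pos <- msh_obs$pos
  g_focal <- genetic_position(map, pos)
  c5 <- g_focal - genetic_position(map, pos - msh_obs$msh5_bp)
  c3 <- genetic_position(map, pos + msh_obs$msh3_bp) - g_focal
  rho5 <- local_rho(map, msh_obs$ter5_pos)
  rho3 <- local_rho(map, msh_obs$ter3_pos)

  chi <- mu * (msh_obs$msh5_bp + msh_obs$msh3_bp) + c5 + c3
  kernel <- 2L - (msh_obs$eoc5 + msh_obs$eoc3)
  beta <- rep(1, nrow(msh_obs))
  two <- kernel == 2L
  beta[two] <- (mu + rho5[two]) * (mu + rho3[two])
  one5 <- kernel == 1L & !msh_obs$eoc5  # 5' side complete
  one3 <- kernel == 1L & !msh_obs$eoc3
  beta[one5] <- mu + rho5[one5]
  beta[one3] <- mu + rho3[one3]

  msh_obs$chi <- chi
  msh_obs$beta <- beta
  msh_obs$kernel <- as.integer(kernel)
  msh_obs
}
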