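#' Simulate a sample of phased chromosomes with recorded genealogy truth
#'
#' Runs a coalescent simulation (via the msprime/tskit Python backend shipped
#' with the package) under one of three demographic models, returning the
#' phased haplotypes together with per-variant-copy genealogical truth: the
#' true first coalescent time t_c of each copy's lineage with any lineage
#' outside the carrier set at the focal position, the sister-branch length
#' phi at that node, and (for singletons simulated without recombination) the
#' distance x_AS to the nearest retained mutation on the focal or sister
#' branch.
#'
#' Demographies: `"constant"` (diploid size `N0`); `"growth"` (exponential
#' growth from 1e4 to 5e5 over the 200 generations before sampling); and
#' `"ooa"`, a three-population out-of-Africa history with bottleneck,
#' migration and recent growth (Gutenkunst et al. 2009 point estimates),
#' sampled from the European deme.
#'
#' @param demography `"constant"`, `"growth"` or `"ooa"`.
#' @param n sampled chromosomes (even; emitted as n/2 phased diploids).
#' @param L_bp simulated sequence length (bp).
#' @param mu per-base per-generation mutation rate.
#' @param rho per-base per-generation recombination rate.
#' @param seed integer random seed; runs are fully reproducible.
#' @param N0 diploid size for the constant demography.
#' @param write_trees also export per-site marginal trees as newick (capped
#'   at `max_tree_sites`; used for cross-checks).
#' @param max_tree_sites cap on exported marginal trees.
#' @param python python interpreter with msprime and tskit importable.
#' @return An object of class `coalescent_sim`: `hm` (a
#'   [haplotype_matrix()] whose rows match the truth's `row` indices),
#'   `truth` (tibble: `pos`, `row`, `k`, `tc`, `phi`, then per direction the
#'   distance to the nearest focal-or-sister-branch mutation `xas5`/`xas3`
#'   and to the nearest focal-branch mutation `xa5`/`xa3`, each with a
#'   window-censoring flag), `trees` (tibble of newick strings or `NULL`)
#'   and the configuration.
#' @export
simulate_sample <- function(demography = c("constant", "growth", "ooa"),
                            n, L_bp, mu, rho, seed, N0 = 1e4,
                            write_trees = FALSE, max_tree_sites = 200L,
                            python = "python") {
  demography <- match.arg(demography)
  stopifnot(n >= 2, n %% 2 == 0, L_bp >= 1, mu >= 0, rho >= 0)
  script <- system.file("python", "simulate_coalescent.py", package = "mshtc")
  if (script == "") stop("simulation backend script not found")
  if (Sys.which(python) == "") {
    stop("python interpreter '", python, "' not found; the simulation ",
         "functions need python with msprime and tskit")
  }
  dir <- tempfile("mshtc_sim")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- list(demography = demography, n = n, L = L_bp, mu = mu, rho = rho,
              seed = as.integer(seed), N0 = N0,
              write_trees = write_trees, max_tree_sites = max_tree_sites)
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  status <- system2(python, c(shQuote(script), shQuote(cfg_path), shQuote(dir)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("simulation backend failed:\n", paste(status, collapse = "\n"))
  }
  vcf_path <- file.path(dir, "sim.vcf")
  truth_path <- file.path(dir, "truth.tsv")
  truth <- utils::read.table(truth_path, header = TRUE, sep = "\t")
  truth <- tibble::tibble(
    pos = as.numeric(truth$pos), row = as.integer(truth$row) + 1L,
    k = as.integer(truth$k), tc = truth$tc, phi = truth$phi,
    xas5 = suppressWarnings(as.numeric(truth$xas5)),
    cens5 = as.logical(truth$cens5),
    xas3 = suppressWarnings(as.numeric(truth$xas3)),
    cens3 = as.logical(truth$cens3),
    xa5 = suppressWarnings(as.numeric(truth$xa5)),
    censa5 = as.logical(truth$censa5),
    xa3 = suppressWarnings(as.numeric(truth$xa3)),
    censa3 = as.logical(truth$censa3)
  )
  hm <- if (file.size(vcf_path) > 0 &&
              length(readLines(vcf_path)) > 5) {
    read_haplotypes(vcf_path, chrom_length_bp = L_bp)
  } else {
    haplotype_matrix(matrix(integer(0), nrow = n, ncol = 0), numeric(0),
                     chrom_length_bp = L_bp)
  }
  trees <- NULL
  tp <- file.path(dir, "trees.nwk")
  if (write_trees && file.exists(tp) && file.size(tp) > 0) {
    tl <- utils::read.table(tp, header = FALSE, sep = "\t",
                            col.names = c("pos", "newick"),
                            stringsAsFactors = FALSE)
    trees <- tibble::as_tibble(tl)
  }
  structure(list(hm = hm, truth = truth, trees = trees, config = cfg),
            class = "coalescent_sim")
}

#' @export
print.coalescent_sim <- function(x, ...) {
  cat(sprintf(
    "<coalescent_sim> %s demography, n = %d chromosomes, L = %s bp\n",
    x$config$demography, x$config$n, format(x$config$L, big.mark = ",")
  ))
  cat(sprintf("  %d variant sites, %d variant copies\n",
              ncol(x$hm$alleles), nrow(x$truth)))
  invisible(x)
}

#' Marginal tree of a simulation at a position
#'
#' @param sim a [simulate_sample()] result built with `write_trees = TRUE`.
#' @param pos a variant position with an exported tree.
#' @return An `ape::phylo` tree; tip `n<j>` is chromosome row `j + 1`.
#' @export
marginal_tree <- function(sim, pos) {
  stopifnot(inherits(sim, "coalescent_sim"))
  if (is.null(sim$trees)) stop("simulation was run without write_trees")
  i <- match(pos, sim$trees$pos)
  if (is.na(i)) stop("no exported tree at position ", pos)
  txt <- sim$trees$newick[i]
  if (!grepl(";\\s*$", txt)) txt <- paste0(txt, ";")
  ape::read.tree(text = txt)
}

#' True first coalescent time and sister-branch length from a genealogy
#'
#' Reads the truth the estimator targets off a (marginal) gene tree: t_c is
#' the time of the first node on the focal tip's root path whose subtree
#' contains a chromosome outside the carrier set, and phi is the length of
#' the sister branch at that node (when the sister subtree is a single leaf,
#' phi equals t_c). Tips are taken to be sampled at time 0, so node times
#' are depths below the highest tip-to-root distance.
#'
#' @param tree an `ape::phylo` with edge lengths (ultrametric).
#' @param focal_tip focal tip label (or index).
#' @param carrier_tips labels of the tips carrying the focal allele
#'   (defaults to the focal tip alone, the singleton/arbitrary-base case).
#' @return A list with `t_c` and `phi` (generations).
#' @export
true_tc_phi <- function(tree, focal_tip, carrier_tips = focal_tip) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  tip_id <- function(x) {
    if (is.character(x)) match(x, tree$tip.label) else as.integer(x)
  }
  focal <- tip_id(focal_tip)
  carriers <- vapply(carrier_tips, tip_id, integer(1))
  if (is.na(focal)) stop("focal tip not found")

  depth <- ape::node.depth.edgelength(tree)      # distance from root
  t_max <- max(depth[seq_len(ntip)])
  node_time <- t_max - depth

  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  children <- split(tree$edge[, 2], tree$edge[, 1])

  n_tips_under <- function(v) {
    cnt <- 0L; stack <- v
    while (length(stack)) {
      u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (u <= ntip) cnt <- cnt + 1L
      else stack <- c(stack, children[[as.character(u)]])
    }
    cnt
  }
  carriers_under <- function(v) {
    cnt <- 0L; stack <- v
    while (length(stack)) {
      u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (u <= ntip) cnt <- cnt + (u %in% carriers)
      else stack <- c(stack, children[[as.character(u)]])
    }
    cnt
  }

  u <- focal
  p <- parent[u]
  while (p != 0L && n_tips_under(p) == carriers_under(p)) {
    u <- p
    p <- parent[u]
  }
  if (p == 0L) stop("every tip carries the allele; no first coalescence")
  t_c <- node_time[p]
  sisters <- setdiff(children[[as.character(p)]], u)
  phi <- max(t_c - node_time[sisters])
  list(t_c = t_c, phi = phi)
}

#' Distance to the nearest focal- or sister-branch mutation
#'
#' x_AS is the physical distance from a focal base to the closest mutation
#' that arose on the focal branch (A) or the sister branch (S); without
#' recombination it upper-bounds the maximum shared haplotype. This helper
#' evaluates it per direction from explicit mutation placements; simulated
#' values come from [simulate_sample()]'s truth table.
#'
#' @param focal_pos focal base position (bp).
#' @param mut_pos_A positions of mutations on branch A.
#' @param mut_pos_S positions of mutations on branch S.
#' @param window assayed region `c(lo, hi)`; a direction with no A/S
#'   mutation is censored at its bound.
#' @return A one-row tibble: `xas5`, `cens5`, `xas3`, `cens3`.
#' @export
extract_xas <- function(focal_pos, mut_pos_A = numeric(0),
                        mut_pos_S = numeric(0), window) {
  mut <- c(mut_pos_A, mut_pos_S)
  left <- mut[mut < focal_pos]
  right <- mut[mut > focal_pos]
  cens5 <- !length(left)
  cens3 <- !length(right)
  tibble::tibble(
    xas5 = if (cens5) focal_pos - window[1] else focal_pos - max(left),
    cens5 = cens5,
    xas3 = if (cens3) window[2] - focal_pos else min(right) - focal_pos,
    cens3 = cens3
  )
}

#' Probability that the msh is not determined by a focal- or sister-branch
#' mutation
#'
#' With exactly two sister chromosomes, the observed maximum shared haplotype
#' falls short of x_AS when both sisters independently acquire a mutation
#' closer to the focal base than any mutation on the focal or sister branch.
#' Averaging over the exponential x_AS distance gives the closed form
#' (phi - t_c)^2 / (t_c (3 t_c - phi)): 1/3 at phi = 0, 1/10 at
#' phi = t_c / 2, and 0 as phi approaches t_c.
#'
#' @param t_c first coalescent time (> 0).
#' @param phi sister branch length, in `[0, t_c]`.
#' @return The probability. Vectorized.
#' @export
prob_msh_not_xas <- function(t_c, phi) {
  if (any(t_c <= 0)) stop("t_c must be > 0")
  if (any(phi < 0 | phi > t_c)) stop("phi must lie in [0, t_c]")
  (phi - t_c)^2 / (t_c * (3 * t_c - phi))
}

#' Monte-Carlo check of the two-sister mutation race
#'
#' Simulates the race behind [prob_msh_not_xas()]: x_AS is exponential with
#' rate mu (t_c + phi) and each of the two sister lineages acquires its
#' nearest private mutation at an exponential distance with rate
#' mu (t_c - phi); the msh differs from x_AS when both private distances are
#' smaller than x_AS. The mutation rate cancels from the probability.
#'
#' @inheritParams prob_msh_not_xas
#' @param reps number of Monte-Carlo replicates.
#' @param seed integer seed.
#' @return A list with the estimated probability `p_hat` and its standard
#'   error `se`.
#' @export
simulate_msh_xas_race <- function(t_c, phi, reps = 1e5, seed = 1) {
  stopifnot(t_c > 0, phi >= 0, phi <= t_c)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (phi == t_c) return(list(p_hat = 0, se = 0))  # sisters cannot mutate first
  x <- stats::rexp(reps, rate = t_c + phi)
  y1 <- stats::rexp(reps, rate = t_c - phi)
  y2 <- stats::rexp(reps, rate = t_c - phi)
  hit <- y1 < x & y2 < x
  p <- mean(hit)
  list(p_hat = p, se = sqrt(p * (1 - p) / reps))
}

#' Expected number of segregating sites under the neutral coalescent
#'
#' Watterson's formula for a constant-size population:
#' E[S] = theta L sum_{i=1}^{n-1} 1/i with theta = 4 N0 mu per bp, and
#' Var[S] = a1 theta L + a2 (theta L)^2 with a2 = sum 1/i^2.
#'
#' @param n sample size (chromosomes).
#' @param L_bp sequence length (bp).
#' @param mu per-base per-generation mutation rate.
#' @param N0 diploid effective size.
#' @return A list with `mean` and `sd` of the segregating-site count.
#' @export
watterson_segsites <- function(n, L_bp, mu, N0) {
  i <- seq_len(n - 1)
  theta <- 4 * N0 * mu * L_bp
  m <- theta * sum(1 / i)
  v <- theta * sum(1 / i) + theta^2 * sum(1 / i^2)
  list(mean = m, sd = sqrt(v))
}
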