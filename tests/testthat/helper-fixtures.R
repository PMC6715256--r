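# shared fixtures built in code

extdata <- function(file) {
  system.file("extdata", file, package = "mshtc")
}

# random binary haplotype matrix with sorted unique positions
random_hm <- function(M, S, seed, p = NULL, span = 10 * S) {
  set.seed(seed)
  if (is.null(p)) p <- stats::runif(1, 0.05, 0.95)
  X <- matrix(stats::rbinom(M * S, 1, p), M, S)
  pos <- sort(sample.int(span, S))
  haplotype_matrix(X, pos)
}

# brute-force comparison for one msh-table row
oracle_matches <- function(hm, tb_row) {
  vc <- variant_carriers(hm, tb_row$site)
  ex <- if (vc$k > 1) setdiff(vc$carriers, tb_row$row) else integer(0)
  bf <- brute_force_msh(hm, tb_row$row, tb_row$site, exclude_rows = ex)
  cols <- c("msh5_bp", "msh3_bp", "eoc5", "eoc3", "partner5", "partner3")
  isTRUE(all.equal(unlist(tb_row[cols]), unlist(bf[1, cols])))
}

# one small shared coalescent simulation, computed once per test run
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_sample("constant", n = 20, L_bp = 5e5, mu = 1e-8,
                                rho = 1e-8, seed = 77, write_trees = TRUE,
                                max_tree_sites = 1000L)
    }
    cache
  }
})

# write a temporary plain-text VCF from header + body lines
write_vcf_lines <- function(body, samples = c("S1", "S2")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=200000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body
  ), path)
  path
}
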