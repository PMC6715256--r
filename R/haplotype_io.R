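#' Construct a haplotype matrix
#'
#' A haplotype matrix holds a binary alignment of phased chromosomes: one row
#' per chromosome, one column per biallelic variant site, with allele 0 the
#' ancestral/reference state and 1 the derived/alternate state. Physical
#' positions are 1-based and strictly increasing.
#'
#' @param alleles integer matrix (chromosomes x sites) of 0/1 alleles.
#' @param positions integer vector of 1-based physical positions, strictly
#'   increasing, one per site column.
#' @param chrom chromosome label.
#' @param sample_ids identifiers of the diploid individuals; each contributes
#'   two consecutive rows. Leave `NULL` for haploid rows named by index.
#' @param chrom_length_bp physical chromosome length. When `NA` (default) the
#'   assayed region is taken to span the first to the last variant position,
#'   and shared-haplotype tracts that reach those bounds are flagged as
#'   truncated there.
#' @param variants optional tibble of per-site records (as produced by
#'   [read_haplotypes()]); rebuilt from the matrix when omitted.
#' @return An object of class `haplotype_matrix`.
#' @seealso [read_haplotypes()], [variant_sites()], [variant_carriers()]
#' @export
haplotype_matrix <- function(alleles, positions, chrom = "1",
                             sample_ids = NULL, chrom_length_bp = NA_real_,
                             variants = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.numeric(positions)
  if (ncol(alleles) != length(positions)) {
    stop("number of allele columns must equal number of positions")
  }
  if (length(positions) > 1 && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  if (length(alleles) && !all(alleles %in% c(0L, 1L))) {
    stop("alleles must be 0 (ancestral) or 1 (derived)")
  }
  if (!is.null(sample_ids) && nrow(alleles) != 2L * length(sample_ids)) {
    stop("diploid input needs 2 chromosome rows per sample_id")
  }
  hm <- structure(
    list(
      alleles = alleles,
      positions = positions,
      chrom = as.character(chrom),
      chrom_length_bp = as.numeric(chrom_length_bp),
      sample_ids = sample_ids
    ),
    class = "haplotype_matrix"
  )
  hm$variants <- if (is.null(variants)) .rebuild_variants(hm) else variants
  hm
}

.rebuild_variants <- function(hm, ref = NULL, alt = NULL) {
  k <- if (nrow(hm$alleles)) as.integer(colSums(hm$alleles)) else integer(0)
  tibble::tibble(
    site = seq_along(hm$positions),
    pos = hm$positions,
    ref = if (is.null(ref)) rep(NA_character_, length(k)) else ref,
    alt = if (is.null(alt)) rep(NA_character_, length(k)) else alt,
    k = k,
    masked = FALSE
  )
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<haplotype_matrix> %d chromosomes x %d sites, chrom %s (%s-%s bp)\n",
    nrow(x$alleles), ncol(x$alleles), x$chrom,
    format(if (length(x$positions)) min(x$positions) else NA),
    format(if (length(x$positions)) max(x$positions) else NA)
  ))
  if (!is.null(x$sample_ids)) {
    cat(sprintf("  %d diploid individuals\n", length(x$sample_ids)))
  }
  nm <- sum(x$variants$masked)
  if (nm > 0) cat(sprintf("  %d masked CpG-transition sites\n", nm))
  invisible(x)
}

#' Per-site variant records
#'
#' @param hm a [haplotype_matrix()].
#' @return A tibble with one row per retained site: `site` (column index),
#'   `pos`, `ref`, `alt`, derived allele count `k`, and the CpG-transition
#'   `masked` flag.
#' @export
variant_sites <- function(hm) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  hm$variants
}

#' Carrier chromosomes of a variant
#'
#' @param hm a [haplotype_matrix()].
#' @param site site column index.
#' @return A list with `carriers` (row indices of chromosomes carrying the
#'   derived allele), allele count `k`, and `valid` (`FALSE` for monomorphic
#'   columns, which cannot be estimation targets).
#' @export
variant_carriers <- function(hm, site) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  if (site < 1 || site > ncol(hm$alleles)) stop("site out of range")
  carriers <- which(hm$alleles[, site] == 1L)
  k <- length(carriers)
  list(carriers = carriers, k = k, valid = k >= 1L && k <= nrow(hm$alleles) - 1L)
}

#' Read phased haplotypes from a VCF file
#'
#' Reads one chromosome of a phased VCF into a [haplotype_matrix()]. Only
#' biallelic SNP records are retained by default; genotypes must use the
#' phased separator `|`.
#'
#' @param vcf_source path to a VCF file (plain text or gzip).
#' @param chrom chromosome to read; `NULL` (default) requires the file to
#'   contain a single chromosome.
#' @param biallelic_snps_only drop records that are multiallelic or not
#'   simple SNPs (default `TRUE`).
#' @param missing policy for missing genotypes: `"error"` (default) or
#'   `"drop_individual"`, which removes both chromosomes of any individual
#'   with a missing call anywhere on the chromosome (per-site dropping would
#'   distort shared-haplotype tracts).
#' @param chrom_length_bp physical chromosome length; when `NA` it is taken
#'   from a `##contig` header line if present, else defaults to the span of
#'   observed variants.
#' @return A [haplotype_matrix()] with its per-site records (see
#'   [variant_sites()]).
#' @export
read_haplotypes <- function(vcf_source, chrom = NULL,
                            biallelic_snps_only = TRUE,
                            missing = c("error", "drop_individual"),
                            chrom_length_bp = NA_real_) {
  missing <- match.arg(missing)
  vcf <- vcfR::read.vcfR(vcf_source, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chroms <- fix[, "CHROM"]
  if (is.null(chrom)) {
    uc <- unique(chroms)
    if (length(uc) > 1) {
      stop("VCF contains several chromosomes (", toString(uc),
           "); pass `chrom`")
    }
    chrom <- uc
  }
  keep <- chroms == chrom
  if (!any(keep)) stop("no records for chromosome ", chrom)

  if (is.na(chrom_length_bp)) {
    meta <- vcf@meta
    ln <- grep(paste0("^##contig=<ID=", chrom, "\\b"), meta, value = TRUE)
    if (length(ln) == 1 && grepl("length=", ln)) {
      chrom_length_bp <- as.numeric(sub(".*length=([0-9]+).*", "\\1", ln))
    }
  }

  ref <- fix[keep, "REF"]
  alt <- fix[keep, "ALT"]
  pos <- as.numeric(fix[keep, "POS"])
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]

  if (biallelic_snps_only) {
    snp <- nchar(ref) == 1L & nchar(alt) == 1L &
      ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
      !grepl(",", alt)
    ref <- ref[snp]; alt <- alt[snp]; pos <- pos[snp]
    gt <- gt[snp, , drop = FALSE]
  }

  miss <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  if (any(miss)) {
    if (missing == "error") {
      idx <- which(miss, arr.ind = TRUE)[1, ]
      stop("missing genotype at position ", pos[idx[1]], " (sample ",
           colnames(gt)[idx[2]], "); use missing = \"drop_individual\"")
    }
    drop_cols <- unique(which(miss, arr.ind = TRUE)[, 2])
    gt <- gt[, -drop_cols, drop = FALSE]
    if (ncol(gt) == 0) stop("all individuals dropped for missing genotypes")
  }

  unphased <- matrix(grepl("/", gt), nrow(gt))
  if (any(unphased)) {
    idx <- which(unphased, arr.ind = TRUE)[1, ]
    stop("unphased genotype '", gt[idx[1], idx[2]], "' at position ",
         pos[idx[1]], " (sample ", colnames(gt)[idx[2]], ")")
  }

  a1 <- suppressWarnings(as.integer(sub("\\|.*", "", gt)))
  a2 <- suppressWarnings(as.integer(sub(".*\\|", "", gt)))
  if (anyNA(a1) || anyNA(a2) || any(a1 > 1) || any(a2 > 1)) {
    stop("genotype fields must be phased biallelic 0|0, 0|1, 1|0 or 1|1")
  }
  n_ind <- ncol(gt)
  alleles <- matrix(0L, nrow = 2L * n_ind, ncol = nrow(gt))
  alleles[seq(1L, 2L * n_ind, by = 2L), ] <- t(matrix(a1, nrow(gt), n_ind))
  alleles[seq(2L, 2L * n_ind, by = 2L), ] <- t(matrix(a2, nrow(gt), n_ind))

  hm <- haplotype_matrix(alleles, pos, chrom = chrom,
                         sample_ids = colnames(gt),
                         chrom_length_bp = chrom_length_bp)
  hm$variants <- .rebuild_variants(hm, ref = ref, alt = alt)
  hm
}

#' Write a haplotype matrix to a plain-text VCF
#'
#' @param hm a [haplotype_matrix()] with diploid rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(hm, path) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  n_row <- nrow(hm$alleles)
  if (n_row %% 2L != 0L) stop("VCF output requires an even number of rows")
  ids <- hm$sample_ids
  if (is.null(ids)) ids <- sprintf("ind%d", seq_len(n_row / 2L))
  v <- hm$variants
  ref <- ifelse(is.na(v$ref), "A", v$ref)
  alt <- ifelse(is.na(v$alt), "T", v$alt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    if (!is.na(hm$chrom_length_bp)) {
      sprintf("##contig=<ID=%s,length=%d>", hm$chrom, as.integer(hm$chrom_length_bp))
    } else {
      sprintf("##contig=<ID=%s>", hm$chrom)
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  odd <- hm$alleles[seq(1L, n_row, by = 2L), , drop = FALSE]
  even <- hm$alleles[seq(2L, n_row, by = 2L), , drop = FALSE]
  for (j in seq_along(hm$positions)) {
    gts <- paste0(odd[, j], "|", even[, j])
    writeLines(paste(c(hm$chrom, format(hm$positions[j], scientific = FALSE),
                       ".", ref[j], alt[j], ".", "PASS", ".", "GT", gts),
                     collapse = "\t"), con)
  }
  invisible(path)
}

.context_lookup <- function(context, positions) {
  # returns data.frame(prev, nxt): reference bases flanking each position
  if (is.character(context) && length(context) == 1 && file.exists(context)) {
    dna <- ape::read.FASTA(context)
    if (length(dna) != 1) stop("reference FASTA must contain one sequence")
    context <- toupper(paste(as.character(as.matrix(dna))[1, ], collapse = ""))
  }
  if (is.character(context) && length(context) == 1) {
    ref_len <- nchar(context)
    prev <- ifelse(positions > 1,
                   substring(context, positions - 1, positions - 1), NA)
    nxt <- ifelse(positions < ref_len,
                  substring(context, positions + 1, positions + 1), NA)
    return(data.frame(prev = toupper(prev), nxt = toupper(nxt)))
  }
  if (is.data.frame(context)) {
    idx <- match(positions, context$pos)
    if (anyNA(idx)) {
      stop("context annotation missing for position ",
           positions[which(is.na(idx))[1]],
           "; supply a reference or disable masking")
    }
    return(data.frame(prev = toupper(context$prev[idx]),
                      nxt = toupper(context$nxt[idx])))
  }
  if (is.function(context)) {
    out <- context(positions)
    return(data.frame(prev = toupper(out$prev), nxt = toupper(out$nxt)))
  }
  stop("context must be a reference sequence/FASTA path, a data frame ",
       "(pos, prev, nxt), or a function; supply one or disable masking")
}

#' Mask CpG/TpG transition variants
#'
#' Flags C>T variants whose reference 3' neighbour is G and G>A variants
#' whose reference 5' neighbour is C. These sites mutate at elevated,
#' heterogeneous rates, so they are excluded as estimation targets under the
#' constant per-base mutation rate model. By default masked columns are
#' removed from the matrix entirely (they neither receive estimates nor
#' terminate shared-haplotype tracts); with `action = "flag"` they are
#' retained in the alignment as tract terminators but skipped as targets.
#'
#' @param hm a [haplotype_matrix()] with `ref`/`alt` filled in.
#' @param context reference context: a single reference sequence string, the
#'   path to a single-record FASTA, a data frame with columns `pos`, `prev`,
#'   `nxt`, or a function of positions returning such a data frame.
#' @param action `"drop"` (default) removes masked columns; `"flag"` keeps
#'   them as terminators only.
#' @return The updated [haplotype_matrix()].
#' @export
mask_cpg_transitions <- function(hm, context, action = c("drop", "flag")) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  action <- match.arg(action)
  if (missing(context) || is.null(context)) {
    stop("CpG masking needs reference context; supply `context` or skip masking")
  }
  v <- hm$variants
  if (all(is.na(v$ref))) stop("variant ref/alt alleles unknown; read from VCF")
  ctx <- .context_lookup(context, v$pos)
  cpg <- (v$ref == "C" & v$alt == "T" & !is.na(ctx$nxt) & ctx$nxt == "G") |
    (v$ref == "G" & v$alt == "A" & !is.na(ctx$prev) & ctx$prev == "C")
  hm$variants$masked <- hm$variants$masked | cpg
  if (action == "drop") hm <- drop_masked_sites(hm) else hm
}

#' Remove masked site columns from a haplotype matrix
#'
#' @param hm a [haplotype_matrix()].
#' @return The matrix restricted to unmasked columns.
#' @export
drop_masked_sites <- function(hm) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  keep <- !hm$variants$masked
  if (all(keep)) return(hm)
  hm$alleles <- hm$alleles[, keep, drop = FALSE]
  hm$positions <- hm$positions[keep]
  hm$variants <- hm$variants[keep, , drop = FALSE]
  hm$variants$site <- seq_len(nrow(hm$variants))
  hm
}

# region bounds used for end-of-chromosome truncation distances
.chrom_bounds <- function(hm) {
  if (!is.na(hm$chrom_length_bp)) {
    c(1, hm$chrom_length_bp)
  } else if (length(hm$positions)) {
    range(hm$positions)
  } else {
    c(1, 1)
  }
}
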