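test_that("phased VCF records transcribe to the haplotype matrix", {
  hm <- read_haplotypes(extdata("example.vcf"))
  expect_s3_class(hm, "haplotype_matrix")
  expect_equal(dim(hm$alleles), c(8L, 10L))
  expect_equal(hm$positions[c(1, 10)], c(5000, 88000))
  expect_equal(hm$chrom_length_bp, 100000)
  # spot-check GT transcription: NA1 = rows 1-2, NA4 = rows 7-8
  expect_equal(hm$alleles[1:2, 1], c(1L, 0L))      # 1|0
  expect_equal(hm$alleles[1:2, 2], c(1L, 1L))      # 1|1
  expect_equal(hm$alleles[7:8, 7], c(1L, 1L))
  expect_equal(hm$alleles[5:6, 4], c(1L, 1L))
  v <- variant_sites(hm)
  expect_equal(v$k, c(1L, 2L, 1L, 3L, 1L, 4L, 2L, 1L, 5L, 2L))
  expect_equal(v$ref[3], "C")
  expect_equal(v$alt[3], "T")
})

test_that("filters drop multiallelic and non-SNP records", {
  body <- c(
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t0|0",
    "1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t0|1\t0|0",   # multiallelic
    "1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t1|0\t0|1",
    "1\t400\t.\tT\tTA\t.\tPASS\t.\tGT\t0|0\t0|1",    # indel
    "1\t500\t.\tT\tA\t.\tPASS\t.\tGT\t0|0\t1|0"
  )
  hm <- read_haplotypes(write_vcf_lines(body))
  expect_equal(ncol(hm$alleles), 3L)
  expect_equal(hm$positions, c(100, 300, 500))
})

test_that("unphased and missing genotypes trigger the configured policy", {
  unphased <- write_vcf_lines("1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0|0")
  expect_error(read_haplotypes(unphased), "unphased")
  miss <- write_vcf_lines(c(
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t0|0",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t.\t1|0"
  ))
  expect_error(read_haplotypes(miss), "missing genotype")
  hm <- read_haplotypes(miss, missing = "drop_individual")
  expect_equal(nrow(hm$alleles), 2L)  # S1 dropped whole-chromosome
  expect_equal(hm$sample_ids, "S2")
})

test_that("VCF round-trip preserves alleles and positions exactly", {
  hm <- read_haplotypes(extdata("example.vcf"))
  path <- tempfile(fileext = ".vcf")
  write_haplotypes(hm, path)
  hm2 <- read_haplotypes(path)
  expect_identical(hm2$alleles, hm$alleles)
  expect_identical(hm2$positions, hm$positions)
  expect_identical(variant_sites(hm2)$ref, variant_sites(hm)$ref)
})

test_that("CpG-transition masking flags exactly the transition SNPs in context", {
  hm <- read_haplotypes(extdata("example.vcf"))
  ctx <- utils::read.table(extdata("example_context.tsv"), header = TRUE)
  flagged <- mask_cpg_transitions(hm, ctx, action = "flag")
  v <- variant_sites(flagged)
  # C>T with 3' G at 18000; G>A with 5' C at 63000; the C>A transversion at
  # 41000 sits in CpG context but is not a transition
  expect_equal(v$pos[v$masked], c(18000, 63000))
  # idempotent
  again <- mask_cpg_transitions(flagged, ctx, action = "flag")
  expect_identical(variant_sites(again)$masked, v$masked)
  # default drops masked columns entirely
  dropped <- mask_cpg_transitions(hm, ctx)
  expect_equal(ncol(dropped$alleles), 8L)
  expect_false(any(dropped$positions %in% c(18000, 63000)))
  # missing context errors with guidance
  expect_error(mask_cpg_transitions(hm, ctx[1:3, ]), "context")
})

test_that("variant_carriers returns carrier rows and flags monomorphic columns", {
  hm <- haplotype_matrix(matrix(c(0, 0, 1, 0,
                                  1, 1, 0, 0,
                                  0, 0, 0, 0), nrow = 4),
                         positions = c(10, 20, 30))
  expect_equal(variant_carriers(hm, 1)[c("carriers", "k")],
               list(carriers = 3L, k = 1L))
  expect_equal(variant_carriers(hm, 2)$carriers, c(1L, 2L))
  vc <- variant_carriers(hm, 3)
  expect_equal(vc$k, 0L)
  expect_false(vc$valid)
  expect_error(variant_carriers(hm, 9), "out of range")
})

test_that("haplotype_matrix enforces its invariants", {
  expect_error(haplotype_matrix(matrix(0:1, 1, 2), c(20, 10)), "increasing")
  expect_error(haplotype_matrix(matrix(c(0, 2), 1, 2), c(10, 20)), "0 .*or 1")
  expect_error(haplotype_matrix(matrix(0L, 3, 1), 10, sample_ids = c("a", "b")),
               "2 chromosome rows")
})
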