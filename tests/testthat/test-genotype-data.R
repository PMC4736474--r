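make_gm <- function(calls, ...) {
  colnames(calls) <- NULL
  geno_matrix(calls, ...)
}

test_that("geno_matrix validates calls, ids and map", {
  expect_error(geno_matrix(matrix(c(0, 3), 1, 2)), "0, 1, 2 or NA")
  expect_error(geno_matrix(matrix(0, 2, 2), ids = c("a", "a")), "unique")
  expect_error(geno_matrix(matrix(0, 2, 2), map = tibble::tibble(
    marker = c("m1", "m2"), chrom = "1", pos = c(2, 1))), "non-decreasing")
})

test_that("VCF coding conventions map to allele counts", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    paste(c("1", "100", "m1", "A", "T", ".", "PASS", ".", "GT",
            "0/1", "1/0"), collapse = "\t"),
    paste(c("1", "200", "m2", "A", "T", ".", "PASS", ".", "GT",
            "1/1", "./."), collapse = "\t")), path)
  gm <- read_genotypes(path)
  expect_equal(unname(gm$calls["s1", ]), c(1, 2))
  expect_equal(unname(gm$calls["s2", ]), c(1, NA))
})

test_that("multi-allelic sites are refused by name", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    paste(c("1", "100", "bad1", "A", "T,G", ".", "PASS", ".", "GT", "0/1"),
          collapse = "\t")), path)
  expect_error(read_genotypes(path), "bad1")
})

test_that("write/read round-trips are exact for both formats", {
  tb <- small_nam(seed = 8, missing_rate = 0.2)
  gm <- tb$observed
  for (fmt in c("vcf", "table")) {
    path <- withr::local_tempfile(
      fileext = if (fmt == "vcf") ".vcf" else ".csv")
    write_genotypes(gm, path, format = fmt)
    back <- read_genotypes(path)
    expect_equal(unname(back$calls), unname(gm$calls))
    expect_equal(back$ids, gm$ids)
    expect_equal(back$map$marker, gm$map$marker)
  }
})

test_that("dosage overlays survive the round trip", {
  tb <- small_nam(seed = 9, missing_rate = 0.25)
  imp <- impute_mode(tb$observed)
  for (fmt in c("vcf", "table")) {
    path <- withr::local_tempfile(
      fileext = if (fmt == "vcf") ".vcf" else ".csv")
    write_genotypes(imp$geno, path, format = fmt)
    back <- read_genotypes(path)
    expect_equal(unname(back$dosage), unname(imp$geno$dosage),
                 tolerance = 1e-5)
  }
})

test_that("minor allele frequency counts non-missing calls only", {
  gm <- make_gm(rbind(c(0, 0, NA), c(0, 0, NA), c(1, 0, NA), c(2, 0, NA)))
  maf <- minor_allele_frequency(gm)
  expect_equal(maf$maf[1], 0.375) # p = 3/8
  expect_equal(maf$maf[2], 0)     # monomorphic
  expect_true(maf$undefined[3])   # all missing
  expect_true(is.na(maf$maf[3]))
})

test_that("heterozygosity proportion counts hets among observed calls", {
  gm <- make_gm(matrix(c(0, 1, 2, 1, NA), 1))
  expect_equal(heterozygosity_proportion(gm), 0.5)
  expect_equal(heterozygosity_proportion(make_gm(matrix(c(0, 2, 2), 1))), 0)
  expect_true(is.na(heterozygosity_proportion(
    make_gm(matrix(NA_real_, 2, 2)))))
})

test_that("repeated markers are counted against earlier map positions", {
  A <- c(0, 1, 2, 0)
  B <- c(2, 2, 0, 1)
  expect_equal(repeated_marker_count(make_gm(cbind(A, B, A))), 1)
  expect_equal(repeated_marker_count(make_gm(cbind(A, B))), 0)
  expect_equal(repeated_marker_count(make_gm(cbind(A, A, A, B))), 2)
  expect_error(repeated_marker_count(make_gm(cbind(c(0, NA, 1, 2), B))),
               "complete")
})

test_that("inject_missing masks the exact count, reproducibly, MCAR", {
  gm <- make_gm(matrix(rbinom(100 * 100, 2, 0.5), 100, 100))
  ms <- inject_missing(gm, 0.2, seed = 42)
  expect_equal(nrow(ms$mask), 2000)
  expect_equal(sum(is.na(ms$geno$calls)), 2000)
  ms2 <- inject_missing(gm, 0.2, seed = 42)
  expect_equal(ms2$mask, ms$mask)
  # unmasked cells unchanged; masked cells were observed before
  idx <- cbind(ms$mask$row, ms$mask$col)
  keep <- ms$geno$calls
  keep[idx] <- gm$calls[idx]
  expect_equal(keep, gm$calls)
  expect_false(anyNA(ms$mask$true_call))
})

test_that("already-missing cells are never selected by the mask", {
  gm <- make_gm(matrix(c(NA, rep(1, 24)), 5, 5))
  for (s in 1:10) {
    ms <- inject_missing(gm, 0.3, seed = s)
    expect_false(any(ms$mask$row == 1 & ms$mask$col == 1))
  }
})

test_that("masked counts are uniform across columns (MCAR, chi-square)", {
  gm <- make_gm(matrix(rbinom(60 * 40, 2, 0.5), 60, 40))
  pvals <- vapply(1:50, function(s) {
    ms <- inject_missing(gm, 0.2, seed = s)
    counts <- tabulate(ms$mask$col, nbins = 40)
    suppressWarnings(stats::chisq.test(counts)$p.value)
  }, numeric(1))
  # a uniform mechanism should not be rejected at alpha = 0.01 overall
  expect_gt(mean(pvals > 0.01), 0.9)
})

test_that("gene content of a non-inbred Mendelian pedigree is fully
           heritable, and permuted content is not", {
  n_sire <- 15
  kids_per <- 19
  ids <- c(paste0("s", 1:n_sire),
           paste0("k", seq_len(n_sire * kids_per)))
  ped <- build_pedigree(tibble::tibble(
    id = ids,
    parent1 = c(rep(NA, n_sire), rep(paste0("s", 1:n_sire),
                                     each = kids_per)),
    parent2 = NA, selfing_generations = 0))
  A <- a_matrix(ped)
  # gene-content heritability of an error-free Mendelian marker is 1 up to
  # sampling noise in the covariance-borne variance split; the median over
  # replicates sits at the boundary
  h2 <- vapply(1:5, function(s) {
    y <- gene_drop_outbred(ped, seed = s)
    marker_heritability(geno_matrix(matrix(y, ncol = 1), ids = ids), A)$h2
  }, numeric(1))
  expect_gte(stats::median(h2), 0.99)
  expect_true(all(h2 > 0.6))
  # permutation destroys the pedigree signal
  y <- gene_drop_outbred(ped, seed = 1)
  gmp <- geno_matrix(matrix(withr::with_seed(2, sample(y)), ncol = 1),
                     ids = ids)
  expect_lte(marker_heritability(gmp, A)$h2, 0.2)
})

test_that("an identity kernel leaves gene-content components confounded
           and is flagged", {
  set.seed(5)
  y <- rbinom(60, 2, 0.5)
  gm <- geno_matrix(matrix(y, ncol = 1))
  A <- diag(60)
  dimnames(A) <- list(gm$ids, gm$ids)
  mh <- marker_heritability(gm, A)
  expect_true(mh$flagged)
})

test_that("zero-variance markers are a precondition error for marker h2", {
  gm <- make_gm(cbind(rep(1, 10), rbinom(10, 2, 0.5)))
  A <- diag(10)
  dimnames(A) <- list(gm$ids, gm$ids)
  expect_error(marker_heritability(gm, A, markers = 1), "no variation")
})

test_that("filter_markers removes non-segregating and low-MAF markers
           with reasons, and is idempotent", {
  set.seed(11)
  calls <- cbind(
    rep(0, 40),                 # monomorphic
    c(rep(0, 38), 1, 1),        # MAF 0.025
    rbinom(40, 2, 0.5))         # kept
  gm <- make_gm(calls)
  res <- filter_markers(gm, A = NULL, maf_min = 0.05)
  expect_equal(sort(res$report$reason),
               sort(c("non-segregating", "low MAF")))
  expect_equal(res$geno$map$marker, "m3")
  res2 <- filter_markers(res$geno, A = NULL, maf_min = 0.05)
  expect_equal(nrow(res2$report), 0)
})

test_that("the marker-heritability filter preferentially removes
           miscall-ridden markers", {
  tb <- small_nam(seed = 3, n_families = 12, ril_per_family = 10,
                  markers_per_chromosome = 15, founder_poly_rate = 0.5)
  A <- a_matrix(tb$pedigree)
  maf <- minor_allele_frequency(tb$geno)
  eligible <- which(maf$maf >= 0.1)
  set.seed(21)
  bad <- sample(eligible, 5)
  gm <- tb$geno
  for (j in bad) {
    flip <- stats::runif(nrow(gm$calls)) < 0.25
    gm$calls[flip, j] <- (gm$calls[flip, j] +
                            sample(1:2, sum(flip), TRUE)) %% 3
  }
  mh <- marker_heritability(gm, A, markers = eligible)
  bad_names <- gm$map$marker[bad]
  is_bad <- mh$marker %in% bad_names
  expect_lt(mean(mh$h2[is_bad]), mean(mh$h2[!is_bad]))
  # with a threshold between the two groups the filter removes the
  # corrupted markers at a far higher rate than the clean ones
  thr <- 0.55
  res <- filter_markers(gm, A, maf_min = 0.05, marker_h2_min = thr)
  removed_h2 <- res$report$marker[res$report$reason ==
                                    "low marker heritability"]
  expect_gt(mean(bad_names %in% removed_h2),
            mean(setdiff(mh$marker, bad_names) %in% removed_h2))
})
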