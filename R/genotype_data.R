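#' Genotype matrix container
#'
#' A light container for a biallelic SNP panel: an individuals-by-markers
#' matrix of alternate-allele counts in `{0, 1, 2, NA}`, an optional
#' continuous dosage overlay in `[0, 2]` for imputed cells, and a marker map
#' (chromosome and ordered position, genetic or synthetic physical).
#'
#' @param calls Numeric/integer matrix, individuals in rows, markers in
#'   columns; values 0, 1, 2 or `NA`.
#' @param map Data frame with columns `marker`, `chrom`, `pos` (one row per
#'   column of `calls`, in order). Defaults to a single chromosome with unit
#'   spacing.
#' @param ids Individual identifiers; default rownames of `calls`.
#' @param dosage Optional numeric matrix of continuous dosages, same shape as
#'   `calls` (`NA` where no dosage is recorded).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, map = NULL, ids = NULL, dosage = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  bad <- !is.na(calls) & !(calls %in% c(0, 1, 2))
  if (any(bad)) {
    stop("genotype calls must be 0, 1, 2 or NA; found e.g. ",
         calls[which(bad)[1L]], call. = FALSE)
  }
  if (is.null(ids)) ids <- rownames(calls)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(calls)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("individual ids must be unique", call. = FALSE)
  if (length(ids) != nrow(calls)) {
    stop("ids length does not match row count", call. = FALSE)
  }
  if (is.null(map)) {
    mk <- colnames(calls)
    if (is.null(mk)) mk <- paste0("m", seq_len(ncol(calls)))
    map <- tibble::tibble(marker = mk, chrom = "1",
                          pos = as.numeric(seq_len(ncol(calls))))
  }
  map <- tibble::as_tibble(map)[, c("marker", "chrom", "pos")]
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.numeric(map$pos)
  if (nrow(map) != ncol(calls)) {
    stop("map rows must equal marker columns", call. = FALSE)
  }
  if (anyDuplicated(map$marker)) {
    stop("marker ids must be unique", call. = FALSE)
  }
  if (any(unlist(tapply(map$pos, map$chrom, function(p) diff(p) < 0)))) {
    stop("marker positions must be non-decreasing within chromosome",
         call. = FALSE)
  }
  dimnames(calls) <- list(ids, map$marker)
  if (!is.null(dosage)) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "double"
    stopifnot(all(dim(dosage) == dim(calls)))
    dimnames(dosage) <- dimnames(calls)
  }
  structure(list(calls = calls, dosage = dosage, ids = ids, map = map),
            class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' @export
print.geno_matrix <- function(x, ...) {
  n_mis <- sum(is.na(x$calls))
  cat("<geno_matrix> ", nrow(x$calls), " individuals x ", ncol(x$calls),
      " markers (", length(unique(x$map$chrom)), " chromosomes), ",
      format(100 * n_mis / length(x$calls), digits = 3), "% missing",
      if (!is.null(x$dosage)) ", with dosage overlay", "\n", sep = "")
  invisible(x)
}

# internal: subset individuals/markers, keeping map aligned
gm_subset <- function(gm, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(gm$calls))
  if (is.null(cols)) cols <- seq_len(ncol(gm$calls))
  geno_matrix(gm$calls[rows, cols, drop = FALSE],
              map = gm$map[cols, , drop = FALSE],
              ids = gm$ids[rows],
              dosage = if (!is.null(gm$dosage))
                gm$dosage[rows, cols, drop = FALSE])
}

## ---------------------------------------------------------------- I/O ----

#' Read genotypes from VCF or the tabular dialect
#'
#' VCF `GT` fields are mapped `0/0 -> 0`, `0/1`/`1/0` -> 1, `1/1 -> 2`,
#' `./.` -> `NA`; a `DS` FORMAT field, when present, is read into the dosage
#' overlay. Only biallelic diploid sites are accepted. The tabular dialect is
#' a CSV of individuals by markers (first column `id`, `NA` = missing) with a
#' companion 3-column map file (`marker, chrom, pos`).
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"table"`.
#' @param map_path Map file for the tabular dialect; default `<path>.map`.
#' @param dosage_path Optional long-format dosage side file for the tabular
#'   dialect; default `<path>.dosage` when it exists.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "table"),
                           map_path = NULL, dosage_path = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "table"
  }
  if (format == "vcf") .read_vcf(path) else {
    .read_table_dialect(path, map_path, dosage_path)
  }
}

.read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) { # single-variant files come back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    stop("multi-allelic site(s) not supported: ",
         paste(fix[multi, "ID"][seq_len(min(3, sum(multi)))], collapse = ", "),
         call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  a1 <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2 <- substr(gt, 3, 3)
  known <- !is.na(gt)
  if (any(known & (!sep %in% c("/", "|") | nchar(gt) < 3))) {
    stop("non-diploid GT encountered", call. = FALSE)
  }
  calls <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ok <- known & a1 %in% c("0", "1") & a2 %in% c("0", "1")
  calls[ok] <- as.numeric(a1[ok]) + as.numeric(a2[ok])
  mk <- fix[, "ID"]
  mk[is.na(mk) | mk == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[
    is.na(mk) | mk == "."]
  map <- tibble::tibble(marker = mk, chrom = fix[, "CHROM"],
                        pos = as.numeric(fix[, "POS"]))
  dosage <- NULL
  fmt <- v@gt[, "FORMAT"]
  if (any(grepl("DS", fmt))) {
    ds <- suppressWarnings(
      vcfR::extract.gt(v, element = "DS", as.numeric = TRUE))
    dosage <- t(ds)
  }
  geno_matrix(t(calls), map = map, dosage = dosage)
}

.read_table_dialect <- function(path, map_path = NULL, dosage_path = NULL) {
  if (is.null(map_path)) map_path <- paste0(path, ".map")
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = "d", id = "c"), progress = FALSE, na = "NA")
  ids <- df$id
  calls <- as.matrix(df[, -1, drop = FALSE])
  map <- NULL
  if (file.exists(map_path)) {
    map <- readr::read_csv(map_path, col_types = "ccd", progress = FALSE)
    map <- map[match(colnames(calls), map$marker), ]
  }
  dosage <- NULL
  if (is.null(dosage_path)) {
    cand <- paste0(path, ".dosage")
    if (file.exists(cand)) dosage_path <- cand
  }
  if (!is.null(dosage_path) && file.exists(dosage_path)) {
    dl <- readr::read_csv(dosage_path, col_types = "ccd", progress = FALSE)
    dosage <- matrix(NA_real_, length(ids), ncol(calls),
                     dimnames = list(ids, colnames(calls)))
    dosage[cbind(match(dl$id, ids), match(dl$marker, colnames(calls)))] <-
      dl$dosage
  }
  geno_matrix(calls, map = map, ids = ids, dosage = dosage)
}

#' Write genotypes to VCF or the tabular dialect
#'
#' The inverse of [read_genotypes()]. VCF output is plain-text v4.2 with
#' synthetic `REF`/`ALT` alleles and a `GT` field (plus `DS` when a dosage
#' overlay is present). Tabular output writes the call matrix as CSV, the map
#' as `<path>.map`, and any dosage overlay as a long-format
#' `<path>.dosage` side file.
#'
#' @param gm A [geno_matrix()].
#' @param path Output file.
#' @param format `"vcf"` or `"table"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("vcf", "table")) {
  format <- match.arg(format)
  if (format == "vcf") .write_vcf(gm, path) else .write_table_dialect(gm, path)
  invisible(path)
}

.write_vcf <- function(gm, path) {
  map <- gm$map
  pos <- map$pos
  # genetic-map (possibly fractional) coordinates get synthetic bp positions
  if (any(pos != round(pos))) pos <- round(pos * 1e4) + 1
  with_ds <- !is.null(gm$dosage)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mmimpute",
    paste0("##contig=<ID=", unique(map$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (with_ds)
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$ids), collapse = "\t")
  )
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(map)), function(j) {
    cl <- gm$calls[, j]
    g <- ifelse(is.na(cl), "./.", gt_code[cl + 1])
    if (with_ds) {
      ds <- gm$dosage[, j]
      ds <- ifelse(is.na(ds), ".", sprintf("%.6g", ds))
      g <- paste(g, ds, sep = ":")
    }
    paste(c(map$chrom[j], format(pos[j], scientific = FALSE), map$marker[j],
            "A", "T", ".", "PASS", ".", if (with_ds) "GT:DS" else "GT", g),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

.write_table_dialect <- function(gm, path) {
  df <- tibble::as_tibble(gm$calls)
  df <- dplyr::bind_cols(tibble::tibble(id = gm$ids), df)
  readr::write_csv(df, path, na = "NA", progress = FALSE)
  readr::write_csv(gm$map, paste0(path, ".map"), progress = FALSE)
  if (!is.null(gm$dosage)) {
    idx <- which(!is.na(gm$dosage), arr.ind = TRUE)
    dl <- tibble::tibble(id = gm$ids[idx[, 1]],
                         marker = gm$map$marker[idx[, 2]],
                         dosage = gm$dosage[idx])
    readr::write_csv(dl, paste0(path, ".dosage"), progress = FALSE)
  }
}

## ----------------------------------------------------- marker summaries ----

#' Per-marker minor allele frequency
#'
#' Allele frequency is computed from non-missing calls only:
#' `p = sum(calls) / (2 * n_obs)`, `MAF = min(p, 1 - p)`. Markers with no
#' observed calls get `NA` and `undefined = TRUE`.
#'
#' @param gm A [geno_matrix()].
#' @return A tibble with `marker`, `n_obs`, `p_alt`, `maf`, `undefined`.
#' @export
minor_allele_frequency <- function(gm) {
  n_obs <- colSums(!is.na(gm$calls))
  p <- colSums(gm$calls, na.rm = TRUE) / (2 * n_obs)
  p[n_obs == 0] <- NA_real_
  tibble::tibble(marker = gm$map$marker, n_obs = as.integer(n_obs),
                 p_alt = unname(p), maf = unname(pmin(p, 1 - p)),
                 undefined = n_obs == 0)
}

#' Proportion of heterozygous calls
#'
#' The fraction of non-missing ordinal calls equal to 1. For an error-free
#' panel of F5 lines from homozygous parents the expectation is
#' `(1/2)^4 = 6.25%` at loci segregating in the cross.
#'
#' @param gm A [geno_matrix()].
#' @return A single proportion, or `NA` if the panel has no observed calls.
#' @export
heterozygosity_proportion <- function(gm) {
  n_obs <- sum(!is.na(gm$calls))
  if (n_obs == 0) return(NA_real_)
  sum(gm$calls == 1, na.rm = TRUE) / n_obs
}

#' Count markers repeated in full linkage disequilibrium
#'
#' Number of markers whose ordinal call vector is identical to at least one
#' earlier marker in map order (so `k` identical copies count `k - 1`).
#' Requires a complete matrix (run after imputation).
#'
#' @param gm A complete [geno_matrix()].
#' @return Integer count.
#' @export
repeated_marker_count <- function(gm) {
  if (anyNA(gm$calls)) {
    stop("repeated_marker_count requires a complete matrix", call. = FALSE)
  }
  key <- apply(gm$calls, 2, paste, collapse = ",")
  sum(duplicated(key))
}

## -------------------------------------------------------- missingness ----

#' Inject missing-completely-at-random genotype calls
#'
#' Deletes a fraction `rate` of the currently non-missing cells uniformly at
#' random (the masking scheme used to create an evaluation dataset with a
#' known standard, emulating `missForest::prodNA`). Exactly
#' `round(rate * n_nonmissing)` cells are masked; already-missing cells are
#' never selected.
#'
#' @param gm A [geno_matrix()].
#' @param rate Fraction in (0, 1).
#' @param seed Optional integer seed for reproducible masks.
#' @return A list with `geno` (the masked panel) and `mask`, a tibble of
#'   masked cells (`row`, `col`, `id`, `marker`, `true_call`) carrying the
#'   seed as an attribute.
#' @export
inject_missing <- function(gm, rate, seed = NULL) {
  stopifnot(rate > 0, rate < 1)
  cells <- which(!is.na(gm$calls))
  n_mask <- round(rate * length(cells))
  pick <- if (is.null(seed)) sample(cells, n_mask) else {
    withr::with_seed(seed, sample(cells, n_mask))
  }
  idx <- arrayInd(pick, dim(gm$calls))
  mask <- tibble::tibble(row = idx[, 1], col = idx[, 2],
                         id = gm$ids[idx[, 1]],
                         marker = gm$map$marker[idx[, 2]],
                         true_call = gm$calls[pick])
  attr(mask, "seed") <- seed
  calls <- gm$calls
  calls[pick] <- NA_real_
  empty <- colSums(!is.na(calls)) == 0
  if (any(empty)) {
    warning("masking left ", sum(empty), " column(s) fully missing: ",
            paste(utils::head(gm$map$marker[empty], 5), collapse = ", "),
            call. = FALSE)
  }
  list(geno = geno_matrix(calls, map = gm$map, ids = gm$ids,
                          dosage = gm$dosage),
       mask = mask)
}

## ------------------------------------------------------------- filters ----

#' Gene-content marker heritability
#'
#' Treats the 0/1/2 gene content of each marker as a quantitative trait and
#' fits the univariate pedigree mixed model
#' `y = 1*mu + Z*gamma + e`, `Var(gamma) = A * sigma2_g`, by REML. Under
#' error-free Mendelian transmission the gene content follows the pedigree
#' and its heritability `sigma2_g / (sigma2_g + sigma2_e)` is near 1;
#' genotyping errors push it down, which is what the quality filter exploits.
#'
#' @param gm A [geno_matrix()].
#' @param A Numerator relationship matrix over `gm$ids` (from [a_matrix()]).
#' @param markers Marker names or indices to fit (default all).
#' @param tol,max_iter REML convergence controls.
#' @return A tibble with `marker`, `h2`, `sigma_g`, `sigma_e`, `converged`,
#'   `flagged` (TRUE when the fit is unidentifiable or did not converge).
#' @export
marker_heritability <- function(gm, A, markers = NULL, tol = 1e-8,
                                max_iter = 100) {
  if (is.null(markers)) markers <- gm$map$marker
  if (is.numeric(markers)) markers <- gm$map$marker[markers]
  A <- A[gm$ids, gm$ids]
  identity_kernel <- .is_identity(A)
  chA <- tryCatch(chol(A), error = function(e)
    chol(A + diag(1e-8, nrow(A))))
  Ainv <- chol2inv(chA)
  ldA <- 2 * sum(log(diag(chA)))
  rows <- purrr::map(markers, function(mk) {
    j <- match(mk, gm$map$marker)
    y <- gm$calls[, j]
    obs <- which(!is.na(y))
    if (length(unique(y[obs])) < 2) {
      stop("marker ", mk, " has no variation among observed calls",
           call. = FALSE)
    }
    spec <- mm_model(matrix(y, ncol = 1), kernel = A, kernel_inv = Ainv,
                     kernel_logdet = ldA)
    fit <- reml_estimate(spec, tol = tol, max_iter = max_iter)
    h2 <- fit$Sg[1, 1] / (fit$Sg[1, 1] + fit$Se[1])
    tibble::tibble(marker = mk, h2 = h2, sigma_g = fit$Sg[1, 1],
                   sigma_e = fit$Se[1], converged = fit$converged,
                   flagged = !fit$converged || !fit$identifiable ||
                     identity_kernel)
  })
  dplyr::bind_rows(rows)
}

.is_identity <- function(A, tol = 1e-10) {
  nrow(A) == ncol(A) && max(abs(A - diag(nrow(A)))) < tol
}

#' Filter markers by segregation, allele frequency and gene-content
#' heritability
#'
#' Removes non-segregating markers, markers with MAF below `maf_min`, and
#' markers whose gene-content heritability (see [marker_heritability()])
#' falls below `marker_h2_min` — the defaults mirror the standard QC of
#' keeping markers with MAF >= 0.05 and marker heritability >= 0.99. High
#' gene-content heritability means the marker's transmission follows the
#' pedigree, so markers failing it are likely miscall-ridden.
#'
#' @inheritParams marker_heritability
#' @param maf_min Minimum minor allele frequency.
#' @param marker_h2_min Minimum gene-content heritability; set to `NULL` (or
#'   pass no `A`) to skip the mixed-model filter.
#' @param drop_nonsegregating Drop monomorphic / fully missing markers first.
#' @return A list with `geno` (filtered panel) and `report`, a tibble of
#'   removed markers and reasons.
#' @export
filter_markers <- function(gm, A = NULL, maf_min = 0.05,
                           marker_h2_min = 0.99,
                           drop_nonsegregating = TRUE) {
  stopifnot(maf_min >= 0, maf_min <= 1)
  report <- tibble::tibble(marker = character(), reason = character(),
                           value = numeric())
  maf <- minor_allele_frequency(gm)
  drop <- rep(FALSE, ncol(gm$calls))
  if (drop_nonsegregating) {
    nonseg <- maf$undefined | (!is.na(maf$maf) & maf$maf == 0)
    report <- dplyr::bind_rows(report, tibble::tibble(
      marker = maf$marker[nonseg], reason = "non-segregating",
      value = maf$maf[nonseg]))
    drop <- drop | nonseg
  }
  low_maf <- !drop & !maf$undefined & maf$maf < maf_min & maf$maf > 0
  report <- dplyr::bind_rows(report, tibble::tibble(
    marker = maf$marker[low_maf], reason = "low MAF",
    value = maf$maf[low_maf]))
  drop <- drop | low_maf
  if (!is.null(A) && !is.null(marker_h2_min)) {
    stopifnot(marker_h2_min >= 0, marker_h2_min <= 1)
    keep_idx <- which(!drop)
    if (length(keep_idx)) {
      mh <- marker_heritability(gm, A, markers = gm$map$marker[keep_idx])
      low_h2 <- mh$h2 < marker_h2_min & !mh$flagged
      report <- dplyr::bind_rows(report, tibble::tibble(
        marker = mh$marker[low_h2], reason = "low marker heritability",
        value = mh$h2[low_h2]))
      drop[keep_idx[low_h2]] <- TRUE
    }
  }
  list(geno = gm_subset(gm, cols = which(!drop)), report = report)
}
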