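#' k-nearest-neighbour genotype imputation
#'
#' Fills each missing cell with the inverse-distance-weighted mean of the
#' `k` most similar individuals that carry the marker. Similarity is
#' root-mean-square Euclidean distance between per-marker standardised
#' (z-scored) calls over the mutually observed markers, i.e.
#' pairwise-complete distances scaled by the number of shared markers.
#'
#' @param gm A [geno_matrix()].
#' @param k Neighbour count (default 10).
#' @param eps Floor added to distances before inverting, so exact
#'   duplicates do not divide by zero.
#' @return An `imputation_result`.
#' @export
impute_knn <- function(gm, k = 10, eps = 1e-6) {
  stopifnot(k >= 1)
  X <- gm$calls
  n <- nrow(X)
  mu <- colMeans(X, na.rm = TRUE)
  sd <- apply(X, 2, stats::sd, na.rm = TRUE)
  sd[is.na(sd) | sd < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd, "/")
  M <- !is.na(Z)
  Z0 <- Z
  Z0[!M] <- 0
  shared <- tcrossprod(M * 1)
  cross <- tcrossprod(Z0)
  sq <- tcrossprod(Z0^2, M * 1) # sum over shared of z_i^2
  D2 <- sq + t(sq) - 2 * cross
  D <- sqrt(pmax(D2, 0) / pmax(shared, 1))
  D[shared == 0] <- Inf
  diag(D) <- Inf
  dosage_fill <- X
  short <- FALSE
  for (j in seq_len(ncol(X))) {
    mis <- which(is.na(X[, j]))
    if (!length(mis)) next
    donors <- which(!is.na(X[, j]))
    for (i in mis) {
      d <- D[i, donors]
      ok <- is.finite(d)
      if (!any(ok)) next
      cand <- donors[ok][order(d[ok])]
      if (length(cand) < k) short <- TRUE
      nb <- cand[seq_len(min(k, length(cand)))]
      w <- 1 / (D[i, nb] + eps)
      dosage_fill[i, j] <- sum(w * X[nb, j]) / sum(w)
    }
  }
  if (short) warning("fewer than k eligible neighbours for some cells; ",
                     "used all available", call. = FALSE)
  .imp_result(gm, dosage_fill, "knn")
}

#' Iterative truncated-SVD genotype imputation
#'
#' Per chromosome, missing cells are initialised at column means and
#' iteratively replaced by their rank-`r` truncated-SVD reconstruction
#' (`M = U D V'` keeping the leading `r` singular triplets) until the
#' largest change falls below `tol`. With `rank = "auto"` the rank is chosen
#' by Owen–Perry bi-cross-validation: the matrix is split into 2 x 2
#' row/column blocks, each block is predicted from the others as
#' `A12 %*% pinv_r(A22) %*% A21`, and the rank minimising the summed
#' held-out reconstruction error wins (smallest rank on ties).
#'
#' @param gm A [geno_matrix()].
#' @param rank Positive integer or `"auto"`.
#' @param max_rank Upper end of the `"auto"` search grid (capped by the
#'   block dimensions).
#' @param tol,max_iter Completion-iteration controls.
#' @param by_chrom Run per chromosome (the standard practice) or on the
#'   whole panel at once.
#' @return An `imputation_result`; diagnostics record the rank used per
#'   chromosome and convergence.
#' @export
impute_svd <- function(gm, rank = "auto", max_rank = 20, tol = 1e-8,
                       max_iter = 500, by_chrom = TRUE) {
  dosage_fill <- gm$calls
  groups <- if (by_chrom) unique(gm$map$chrom) else "all"
  diags <- purrr::map_dfr(groups, function(chr) {
    jj <- if (by_chrom) which(gm$map$chrom == chr) else
      seq_len(ncol(gm$calls))
    X <- gm$calls[, jj, drop = FALSE]
    Xc <- .mean_complete(X)
    r <- rank
    if (identical(rank, "auto")) {
      grid <- seq_len(max(1, min(max_rank, min(dim(Xc)) - 1)))
      r <- .bcv_rank(Xc, grid)
    }
    res <- .svd_complete(X, Xc, r, tol, max_iter)
    dosage_fill[, jj] <<- res$X
    tibble::tibble(chrom = chr, rank = r, converged = res$converged,
                   iterations = res$iterations)
  })
  .imp_result(gm, dosage_fill, "svd", diagnostics = diags)
}

.mean_complete <- function(X) {
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- mean(X, na.rm = TRUE)
  if (is.nan(cm[1]) || anyNA(cm)) cm[is.na(cm)] <- 1
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- cm[idx[, 2]]
  X
}

.svd_trunc <- function(X, r) {
  r <- min(r, dim(X))
  s <- svd(X, nu = r, nv = r)
  s$u %*% (s$d[seq_len(r)] * t(s$v))
}

.svd_complete <- function(X, Xc, r, tol, max_iter) {
  miss <- is.na(X)
  if (!any(miss)) {
    return(list(X = Xc, converged = TRUE, iterations = 0L))
  }
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    recon <- .svd_trunc(Xc, r)
    delta <- max(abs(recon[miss] - Xc[miss]))
    Xc[miss] <- recon[miss]
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(X = Xc, converged = converged, iterations = it)
}

# Owen-Perry 2x2 bi-cross-validation rank choice on a complete matrix;
# deterministic interleaved row/column blocks.
.bcv_rank <- function(X, grid) {
  rb <- list(seq(1, nrow(X), by = 2), seq(2, nrow(X), by = 2))
  cb <- list(seq(1, ncol(X), by = 2), seq(2, ncol(X), by = 2))
  err <- stats::setNames(numeric(length(grid)), grid)
  for (ri in 1:2) {
    for (ci in 1:2) {
      r1 <- rb[[ri]]
      r2 <- setdiff(seq_len(nrow(X)), r1)
      c1 <- cb[[ci]]
      c2 <- setdiff(seq_len(ncol(X)), c1)
      A11 <- X[r1, c1, drop = FALSE]
      A12 <- X[r1, c2, drop = FALSE]
      A21 <- X[r2, c1, drop = FALSE]
      A22 <- X[r2, c2, drop = FALSE]
      s <- svd(A22)
      for (g in seq_along(grid)) {
        r <- grid[g]
        keep <- seq_len(min(r, length(s$d)))
        dinv <- ifelse(s$d[keep] > 1e-9 * s$d[1], 1 / s$d[keep], 0)
        pinv <- s$v[, keep, drop = FALSE] %*%
          (dinv * t(s$u[, keep, drop = FALSE]))
        err[g] <- err[g] + sum((A11 - A12 %*% pinv %*% A21)^2)
      }
    }
  }
  as.integer(names(err)[which(err <= min(err) * (1 + 1e-8))[1]])
}

#' Modal-call genotype imputation
#'
#' Fills each missing cell with the modal observed call of its column, or of
#' its family's segment of the column; ties break to the lower call. A
#' degenerate baseline (and the fallback the mixed-model imputer uses when a
#' window cannot be fitted).
#'
#' @param gm A [geno_matrix()].
#' @param per `"column"` or `"family"`.
#' @param families Named family labels over `gm$ids` (required for
#'   `per = "family"`).
#' @return An `imputation_result`.
#' @export
impute_mode <- function(gm, per = c("column", "family"), families = NULL) {
  per <- match.arg(per)
  if (per == "family" && is.null(families)) {
    stop("per = 'family' needs family labels", call. = FALSE)
  }
  mode_call <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    tab <- table(factor(v, levels = c(0, 1, 2)))
    as.numeric(names(tab)[which.max(tab)]) # which.max takes first = lowest
  }
  dosage_fill <- gm$calls
  for (j in seq_len(ncol(gm$calls))) {
    mis <- which(is.na(gm$calls[, j]))
    if (!length(mis)) next
    col_mode <- mode_call(gm$calls[, j])
    if (per == "column") {
      dosage_fill[mis, j] <- col_mode
    } else {
      fam <- families[gm$ids]
      fam_modes <- tapply(gm$calls[, j], fam, mode_call)
      fill <- fam_modes[fam[mis]]
      fill[is.na(fill)] <- col_mode
      dosage_fill[mis, j] <- fill
    }
  }
  .imp_result(gm, dosage_fill, paste0("mode-", per))
}

#' Run an external imputation tool through a file adapter
#'
#' Writes the panel in the tool's expected format, substitutes `{input}` /
#' `{output}` into the command template, runs it, and parses the completed
#' panel back. An absent executable yields a skip status rather than an
#' error, so optional tools (HMM imputers, random forest) never break a
#' pipeline; a nonzero exit or unparseable output does error, with the
#' captured log attached.
#'
#' @param gm A [geno_matrix()].
#' @param command Command template containing `{input}` and `{output}`
#'   placeholders; its first token is the executable checked for presence.
#' @param format `"table"` or `"vcf"` interchange format.
#' @param workdir Scratch directory (default a session temp dir).
#' @return An `imputation_result` (with `status = "ok"`), or a list of class
#'   `external_skip` with `status = "skipped"` when the executable is
#'   absent.
#' @export
impute_external <- function(gm, command, format = c("table", "vcf"),
                            workdir = NULL) {
  format <- match.arg(format)
  exe <- strsplit(trimws(command), "\\s+")[[1]][1]
  if (Sys.which(exe) == "" && !file.exists(exe)) {
    return(structure(list(status = "skipped", tool = exe,
                          reason = "executable not found"),
                     class = "external_skip"))
  }
  if (is.null(workdir)) workdir <- tempfile("external_imputer_")
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "vcf") ".vcf" else ".csv"
  input <- file.path(workdir, paste0("input", ext))
  output <- file.path(workdir, paste0("output", ext))
  write_genotypes(gm, input, format = format)
  cmd <- gsub("{output}", output, gsub("{input}", input, command,
                                       fixed = TRUE), fixed = TRUE)
  log <- suppressWarnings(system(paste(cmd, "2>&1"), intern = TRUE))
  status <- attr(log, "status")
  if (!is.null(status) && status != 0) {
    stop("external imputer exited with status ", status, ":\n",
         paste(utils::tail(log, 20), collapse = "\n"), call. = FALSE)
  }
  if (!file.exists(output)) {
    stop("external imputer produced no output file:\n",
         paste(utils::tail(log, 20), collapse = "\n"), call. = FALSE)
  }
  out <- tryCatch(read_genotypes(output, format = format),
                  error = function(e) {
                    stop("could not parse external imputer output: ",
                         conditionMessage(e), call. = FALSE)
                  })
  out <- gm_subset(out, rows = match(gm$ids, out$ids),
                   cols = match(gm$map$marker, out$map$marker))
  fill <- out$calls
  if (!is.null(out$dosage)) {
    keep <- !is.na(out$dosage)
    fill[keep] <- out$dosage[keep]
  }
  res <- .imp_result(gm, fill, "external")
  res$status <- "ok"
  res$log <- log
  res
}
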