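#' Round continuous dosages to ordinal genotype calls
#'
#' Dosages are clipped to `[0, 2]` and binned: `< 0.5 -> 0`,
#' `[0.5, 1.5) -> 1`, `>= 1.5 -> 2` (boundary values go to the
#' heterozygote-side bin, fixed for determinism).
#'
#' @param dosages Numeric vector/matrix of finite dosages.
#' @return Ordinal calls with the same shape.
#' @export
round_dosages <- function(dosages) {
  stopifnot(all(is.finite(dosages) | is.na(dosages)))
  d <- pmin(pmax(dosages, 0), 2)
  out <- ifelse(d < 0.5, 0, ifelse(d < 1.5, 1, 2))
  if (is.matrix(dosages)) dim(out) <- dim(dosages)
  out
}

# assemble an imputation_result from the original panel plus imputed dosages
# at the originally-missing cells
.imp_result <- function(gm, dosage_fill, method, diagnostics = NULL) {
  miss <- is.na(gm$calls)
  calls <- gm$calls
  dosage <- matrix(NA_real_, nrow(calls), ncol(calls),
                   dimnames = dimnames(calls))
  calls[miss] <- round_dosages(dosage_fill[miss])
  dosage[miss] <- pmin(pmax(dosage_fill[miss], 0), 2)
  idx <- which(miss, arr.ind = TRUE)
  structure(list(
    geno = geno_matrix(calls, map = gm$map, ids = gm$ids, dosage = dosage),
    imputed = tibble::tibble(row = idx[, 1], col = idx[, 2],
                             id = gm$ids[idx[, 1]],
                             marker = gm$map$marker[idx[, 2]],
                             dosage = dosage[miss],
                             call = calls[miss]),
    method = method,
    diagnostics = diagnostics
  ), class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("<imputation_result> method '", x$method, "': ", nrow(x$imputed),
      " cells imputed across ", length(unique(x$imputed$marker)),
      " markers\n", sep = "")
  invisible(x)
}

#' Empirical-Bayes prediction of missing calls in one marker window
#'
#' Fits the window's response block (focal marker plus available flanking
#' markers, as continuous 0/1/2 gene content) to the multitrait pedigree
#' model via [reml_estimate()] and predicts the focal marker's missing
#' entries as `mu_j + gamma_j` from [solve_mme()] — the empirical-Bayes
#' (BLUP) estimate that borrows strength from relatives through the kernel
#' and from flanking markers through the genetic covariances.
#'
#' @param Y Numeric `n x t` response block (`NA` = missing); all rows must
#'   be covered by `kernel`.
#' @param kernel Relationship matrix (pedigree `A`).
#' @param focal Column of `Y` to impute.
#' @param tol,max_iter REML controls (see [reml_estimate()]; `tol = 1e-8` by
#'   default for the sliding window, `1e-11` for strict estimation).
#' @param init Optional starting values (warm start from the previous
#'   window).
#' @param kernel_inv,kernel_logdet Optional cached kernel inverse pieces.
#' @return A list: `dosage` (length-n vector, predictions at all
#'   individuals), `fit` (the `reml_fit`), `degenerate` (`TRUE` when the
#'   window had no usable variation and the observed mean was returned).
#' @export
impute_window <- function(Y, kernel, focal = 1, tol = 1e-8, max_iter = 100,
                          init = NULL, kernel_inv = NULL,
                          kernel_logdet = NULL) {
  Y <- as.matrix(Y)
  yj <- Y[, focal]
  obs_mean <- mean(yj, na.rm = TRUE)
  # traits need >= 2 observed calls and some variation to enter the model
  usable <- vapply(seq_len(ncol(Y)), function(a) {
    o <- stats::na.omit(Y[, a])
    length(o) >= 2 && stats::var(o) > 1e-12
  }, logical(1))
  if (!usable[focal]) {
    return(list(dosage = rep(obs_mean, nrow(Y)), fit = NULL,
                degenerate = TRUE))
  }
  keep <- which(usable)
  keep <- c(focal, setdiff(keep, focal))  # focal first
  if (!is.null(init) && nrow(as.matrix(init$Sg)) != length(keep)) {
    init <- NULL
  }
  spec <- mm_model(Y[, keep, drop = FALSE], kernel = kernel,
                   kernel_inv = kernel_inv, kernel_logdet = kernel_logdet)
  fit <- reml_estimate(spec, tol = tol, max_iter = max_iter, init = init)
  sol <- solve_mme(spec, fit)
  list(dosage = sol$fitted[, 1], fit = fit, degenerate = FALSE)
}

#' Sliding-window multivariate mixed-model imputation
#'
#' The pedigree-based imputer: for every marker with missing calls, the
#' marker and its two flanking neighbours on the genetic map form a
#' trivariate response block `Y = {y_i, y_j, y_k}` fitted to
#' `Y = 1 mu + Z gamma + e` with `Var(vec(gamma)) = Sigma_g (x) A` and a
#' diagonal residual block; missing focal entries are replaced by their
#' empirical-Bayes estimates and the window slides to the next marker.
#' Windows always use the original observed data (imputed values are never
#' fed forward), edge markers fall back to a bivariate window, and a
#' single-marker chromosome to the univariate pedigree model. If a window's
#' REML fit fails, the marker falls back to family-mean (or column-mean)
#' imputation, recorded in the diagnostics.
#'
#' @param gm A [geno_matrix()] with markers ordered along the map.
#' @param A Numerator relationship matrix covering `gm$ids` (extra
#'   individuals are dropped).
#' @param families Optional named family labels over `gm$ids`, used only for
#'   the fallback imputation.
#' @param tol Per-window REML tolerance; default `1e-8` (configurable to
#'   `1e-11` for strict reproduction at the cost of extra iterations).
#' @param max_iter Per-window REML iteration cap.
#' @param diagnostics_all Also fit windows for markers without missing
#'   calls, recording their variance components (slower; off by default
#'   since complete markers are passed through unchanged).
#' @return An `imputation_result`: completed panel (ordinal calls plus
#'   continuous dosages for imputed cells), the imputed-cell table, and
#'   per-marker diagnostics (`converged`, `sigma2_g`, `sigma2_e`,
#'   `n_imputed`, `fallback`).
#' @export
impute_mmm <- function(gm, A, families = NULL, tol = 1e-8, max_iter = 30,
                       diagnostics_all = FALSE) {
  missing_ids <- setdiff(gm$ids, rownames(A))
  if (length(missing_ids)) {
    stop("relationship matrix does not cover: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  A <- A[gm$ids, gm$ids]
  ch <- tryCatch(chol(A), error = function(e)
    chol(A + diag(1e-8, nrow(A))))
  Ainv <- chol2inv(ch)
  ldA <- 2 * sum(log(diag(ch)))
  dosage_fill <- gm$calls
  diags <- list()
  chroms <- unique(gm$map$chrom)
  for (chr in chroms) {
    jj <- which(gm$map$chrom == chr)
    warm <- NULL
    for (w in seq_along(jj)) {
      j <- jj[w]
      n_missing <- sum(is.na(gm$calls[, j]))
      if (n_missing == 0 && !diagnostics_all) next
      win <- jj[max(1, w - 1):min(length(jj), w + 1)]
      win <- c(j, setdiff(win, j))
      Y <- gm$calls[, win, drop = FALSE]
      res <- tryCatch(
        impute_window(Y, kernel = A, focal = 1, tol = tol,
                      max_iter = max_iter, init = warm,
                      kernel_inv = Ainv, kernel_logdet = ldA),
        error = function(e) NULL)
      fallback <- is.null(res)
      if (fallback) {
        fill <- .family_mean_fill(gm$calls[, j], families, gm$ids)
      } else if (res$degenerate) {
        fill <- rep(mean(gm$calls[, j], na.rm = TRUE), nrow(gm$calls))
      } else {
        fill <- res$dosage
        warm <- list(Sg = res$fit$Sg, Se = res$fit$Se)
      }
      if (n_missing > 0) {
        mis <- is.na(gm$calls[, j])
        dosage_fill[mis, j] <- fill[mis]
      }
      diags[[length(diags) + 1L]] <- tibble::tibble(
        marker = gm$map$marker[j],
        converged = if (fallback || res$degenerate) NA else
          res$fit$converged,
        sigma2_g = if (fallback || res$degenerate) NA_real_ else
          res$fit$Sg[1, 1],
        sigma2_e = if (fallback || res$degenerate) NA_real_ else
          res$fit$Se[1],
        n_imputed = n_missing,
        fallback = if (fallback) "family-mean" else
          if (res$degenerate) "column-mean" else "none")
    }
  }
  .imp_result(gm, dosage_fill, "mmm", diagnostics = dplyr::bind_rows(diags))
}

# family-mean (falling back to column-mean) fill for one marker
.family_mean_fill <- function(y, families, ids) {
  col_mean <- mean(y, na.rm = TRUE)
  if (is.nan(col_mean)) col_mean <- 1
  fill <- rep(col_mean, length(y))
  if (!is.null(families)) {
    fam <- families[ids]
    fm <- tapply(y, fam, mean, na.rm = TRUE)
    fv <- fm[fam]
    fill[!is.na(fv) & !is.nan(fv)] <- fv[!is.na(fv) & !is.nan(fv)]
  }
  fill
}
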