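#' Imputation accuracy against a standard panel
#'
#' The proportion of imputed cells whose rounded ordinal call is identical
#' to the standard dataset's call, evaluated over the masked cells only.
#'
#' @param imputed An `imputation_result` or completed [geno_matrix()].
#' @param standard The reference [geno_matrix()] (same shape and id order).
#' @param mask The mask tibble from [inject_missing()] (or any tibble with
#'   `row`/`col` columns).
#' @return A proportion in `[0, 1]`, or `NA` for an empty mask.
#' @export
imputation_accuracy <- function(imputed, standard, mask) {
  gm <- if (inherits(imputed, "imputation_result")) imputed$geno else imputed
  stopifnot(all(dim(gm) == dim(standard)), all(gm$ids == standard$ids))
  if (nrow(mask) == 0) return(NA_real_)
  idx <- cbind(mask$row, mask$col)
  mean(gm$calls[idx] == standard$calls[idx])
}

#' Genomic relationship matrix (VanRaden)
#'
#' `G = W W' / (2 * sum(p (1 - p)))` with marker columns centred by twice
#' the allele frequency estimated from the matrix itself. Continuous
#' dosages, where recorded, are used in place of the rounded calls so that
#' imputation uncertainty propagates into the kernel.
#'
#' @param gm A complete [geno_matrix()] (post-imputation).
#' @return A symmetric PSD matrix with individual ids as dimnames.
#' @export
vanraden_g <- function(gm) {
  M <- gm$calls
  if (!is.null(gm$dosage)) {
    keep <- !is.na(gm$dosage)
    M[keep] <- gm$dosage[keep]
  }
  if (anyNA(M)) stop("genomic relationship needs a complete matrix",
                     call. = FALSE)
  p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom < 1e-12) {
    stop("all markers monomorphic; genomic relationship undefined",
         call. = FALSE)
  }
  W <- sweep(M, 2, 2 * p)
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(gm$ids, gm$ids)
  G
}

#' Intra-class-correlation heritability from a mixed model
#'
#' Fits `y = mu + environment + (controls) + additive + e` with the additive
#' effect structured by a relationship kernel (pedigree `A` or genomic `G`)
#' by REML, and returns the narrow-sense heritability
#' `h2 = sigma2_A / (sigma2_A + sigma2_E + sigma2_C + sigma2_e)` — the
#' intra-class correlation that measures how much genetic variation the
#' panel behind the kernel captures. The standard error of `h2` comes from
#' the inverse average-information matrix by the delta method.
#'
#' @param phenotypes Tibble with columns `id`, `env`, `value`, and
#'   optionally `control` (micro-environment grouping); one row per record.
#' @param kernel Relationship matrix whose row names cover the phenotyped
#'   ids.
#' @param tol REML convergence criterion (default the strict `1e-11`).
#' @param max_iter Iteration cap.
#' @return An object of class `heritability_fit`: `h2`, `h2_se`,
#'   `components` tibble, `converged`, and the underlying `vc_fit`.
#' @export
estimate_heritability <- function(phenotypes, kernel, tol = 1e-11,
                                  max_iter = 300) {
  phenotypes <- tibble::as_tibble(phenotypes)
  stopifnot(all(c("id", "env", "value") %in% names(phenotypes)))
  if (length(unique(phenotypes$env)) < 2) {
    stop("need >= 2 environments to separate environmental variance",
         call. = FALSE)
  }
  missing_ids <- setdiff(unique(phenotypes$id), rownames(kernel))
  if (length(missing_ids)) {
    stop("kernel does not cover phenotyped ids: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  ids <- intersect(rownames(kernel), unique(phenotypes$id))
  K <- kernel[ids, ids]
  random <- list(env = phenotypes$env)
  if ("control" %in% names(phenotypes) &&
      length(unique(phenotypes$control)) > 1) {
    random$control <- as.character(phenotypes$control)
  }
  random$additive <- list(factor = phenotypes$id, kernel = K)
  spec <- vc_model(phenotypes$value, random = random)
  fit <- reml_vc(spec, tol = tol, max_iter = max_iter)
  s2 <- fit$sigma2
  total <- sum(s2)
  h2 <- unname(s2["additive"] / total)
  h2_se <- NA_real_
  if (!is.null(fit$ai)) {
    V <- tryCatch(solve(fit$ai), error = function(e) NULL)
    if (!is.null(V)) {
      g <- rep(-s2["additive"] / total^2, length(s2))
      g[names(s2) == "additive"] <- (total - s2["additive"]) / total^2
      h2_se <- sqrt(drop(t(g) %*% V %*% g))
    }
  }
  comp_names <- c(additive = "sigma2_A", env = "sigma2_E",
                  control = "sigma2_C", residual = "sigma2_e")
  components <- tibble::tibble(
    component = unname(comp_names[names(s2)]),
    term = names(s2),
    estimate = unname(s2))
  structure(list(h2 = h2, h2_se = h2_se, components = components,
                 converged = fit$converged, fit = fit),
            class = "heritability_fit")
}

#' @export
print.heritability_fit <- function(x, ...) {
  cat("<heritability_fit> h2 =", format(x$h2, digits = 4),
      if (!is.na(x$h2_se)) paste0("(SE ", format(x$h2_se, digits = 3), ")"),
      "|", if (x$converged) "converged" else "NOT converged", "\n")
  print(x$components)
  invisible(x)
}

#' Cross-validated genomic prediction accuracy
#'
#' Five-fold cross-validation of ridge-type GBLUP: individuals are
#' partitioned into folds (seeded), each fold's genetic values are predicted
#' from the remaining folds through the genomic kernel, and accuracy is the
#' correlation between adjusted observed phenotypes (individual means after
#' removing the training model's environment effects) and predicted genetic
#' values, divided by the square root of the training-data heritability.
#'
#' @param gm A complete [geno_matrix()] used to build the kernel (ignored
#'   when `kernel` is supplied).
#' @param phenotypes Tibble `id`, `env`, `value`.
#' @param kernel Optional precomputed relationship matrix; default
#'   [vanraden_g()] of `gm`.
#' @param folds Number of folds.
#' @param seed Seed for the fold partition.
#' @param tol REML tolerance for the per-fold fits.
#' @return A list of class `cv_accuracy`: `accuracy` (mean over folds),
#'   `folds` tibble (`fold`, `cor`, `h2_train`, `accuracy`), and the guard
#'   flag `undefined` (heritability below 0.01 in some fold).
#' @export
prediction_accuracy_cv <- function(gm, phenotypes, kernel = NULL, folds = 5,
                                   seed = 1, tol = 1e-8) {
  phenotypes <- tibble::as_tibble(phenotypes)
  if (is.null(kernel)) kernel <- vanraden_g(gm)
  kernel <- kernel + diag(1e-6, nrow(kernel)) # numerical PD guard
  ids <- intersect(rownames(kernel), unique(phenotypes$id))
  if (length(ids) < folds * 5) {
    stop("need at least ", folds * 5, " phenotyped individuals",
         call. = FALSE)
  }
  fold_of <- withr::with_seed(seed, {
    stats::setNames(sample(rep_len(seq_len(folds), length(ids))), ids)
  })
  res <- purrr::map_dfr(seq_len(folds), function(f) {
    test_ids <- ids[fold_of == f]
    train <- phenotypes[phenotypes$id %in% ids[fold_of != f], ]
    spec <- vc_model(train$value, random = list(
      env = train$env,
      additive = list(factor = train$id, kernel = kernel[ids, ids])))
    fit <- reml_vc(spec, tol = tol)
    s2 <- fit$sigma2
    h2 <- unname(s2["additive"] / sum(s2))
    env_blup <- fit$u$env
    test <- phenotypes[phenotypes$id %in% test_ids, ]
    adj <- test$value - fit$beta[1] -
      ifelse(test$env %in% names(env_blup), env_blup[test$env], 0)
    adj_mean <- tapply(adj, test$id, mean)
    pred <- fit$u$additive[names(adj_mean)]
    r <- stats::cor(as.numeric(adj_mean), as.numeric(pred))
    tibble::tibble(fold = f, cor = r, h2_train = h2,
                   accuracy = if (h2 >= 0.01) r / sqrt(h2) else NA_real_)
  })
  structure(list(accuracy = mean(res$accuracy, na.rm = TRUE),
                 folds = res,
                 undefined = anyNA(res$accuracy)),
            class = "cv_accuracy")
}

#' @export
print.cv_accuracy <- function(x, ...) {
  cat("<cv_accuracy>", nrow(x$folds), "folds; accuracy =",
      format(x$accuracy, digits = 4), "\n")
  invisible(x)
}

#' Compare imputation methods on a masked panel
#'
#' Runs each requested imputer on MCAR-masked copies of a truth panel and
#' assembles the quality report: imputation accuracy, post-imputation
#' heterozygosity, repeated-marker (full-LD) count, and — when phenotypes
#' are supplied — the heritability and cross-validated prediction accuracy
#' obtained with a genomic kernel built from each method's completed panel.
#' A failing method is recorded as an `NA` row and the run continues.
#'
#' @param truth Complete, error-free [geno_matrix()] standard.
#' @param A Numerator relationship matrix (needed for the `"mmm"` method
#'   and for pedigree-based heritability).
#' @param methods Character subset of `"mmm"`, `"knn"`, `"svd"`, `"mode"`,
#'   `"truth"` (oracle passthrough), or named functions
#'   `function(gm) -> imputation_result`.
#' @param rates MCAR masking rates to evaluate.
#' @param phenotypes Optional phenotype tibble (`id`, `env`, `value`).
#' @param families Optional family labels (mmm fallback, family mode).
#' @param seed Base seed; each rate uses a derived seed so masks are
#'   reproducible.
#' @param knn_k,svd_rank,mmm_tol Method settings passed through.
#' @return A tibble of class `quality_report`, one row per method x rate.
#' @export
compare_methods <- function(truth, A = NULL,
                            methods = c("mmm", "knn", "svd", "mode"),
                            rates = 0.2, phenotypes = NULL, families = NULL,
                            seed = 1, knn_k = 10, svd_rank = "auto",
                            mmm_tol = 1e-8) {
  runners <- list(
    mmm = function(gm) impute_mmm(gm, A, families = families,
                                  tol = mmm_tol),
    knn = function(gm) impute_knn(gm, k = knn_k),
    svd = function(gm) impute_svd(gm, rank = svd_rank),
    mode = function(gm) impute_mode(gm),
    truth = function(gm) .imp_result(gm, truth$calls, "truth")
  )
  if (is.list(methods)) {
    runners <- utils::modifyList(runners, methods[vapply(methods,
                                                         is.function,
                                                         logical(1))])
    methods <- names(methods)
  }
  rows <- list()
  for (ri in seq_along(rates)) {
    rate <- rates[ri]
    masked <- inject_missing(truth, rate, seed = seed + ri - 1L)
    for (m in methods) {
      res <- tryCatch(runners[[m]](masked$geno), error = function(e) e)
      if (inherits(res, "error") || inherits(res, "external_skip")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          method = m, rate = rate, accuracy = NA_real_, het = NA_real_,
          repeated_markers = NA_integer_, h2 = NA_real_,
          prediction_accuracy = NA_real_,
          status = if (inherits(res, "error"))
            conditionMessage(res) else "skipped")
        next
      }
      gm_out <- res$geno
      h2 <- NA_real_
      pacc <- NA_real_
      if (!is.null(phenotypes)) {
        G <- tryCatch(vanraden_g(gm_out), error = function(e) NULL)
        if (!is.null(G)) {
          h2 <- tryCatch(estimate_heritability(
            phenotypes, G + diag(1e-6, nrow(G)), tol = 1e-8)$h2,
            error = function(e) NA_real_)
          pacc <- tryCatch(prediction_accuracy_cv(
            gm_out, phenotypes, kernel = G, seed = seed)$accuracy,
            error = function(e) NA_real_)
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = m, rate = rate,
        accuracy = imputation_accuracy(res, truth, masked$mask),
        het = heterozygosity_proportion(gm_out),
        repeated_markers = as.integer(repeated_marker_count(gm_out)),
        h2 = h2, prediction_accuracy = pacc, status = "ok")
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("quality_report", class(out))
  attr(out, "seed") <- seed
  out
}
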