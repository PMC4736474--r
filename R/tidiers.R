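#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for fitted objects
#'
#' `tidy()` returns one row per estimated quantity; `glance()` returns a
#' one-row model summary — the broom conventions.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @name mmimpute-tidiers
NULL

#' @rdname mmimpute-tidiers
#' @method tidy heritability_fit
#' @export
tidy.heritability_fit <- function(x, ...) x$components

#' @rdname mmimpute-tidiers
#' @method glance heritability_fit
#' @export
glance.heritability_fit <- function(x, ...) {
  wide <- stats::setNames(x$components$estimate, x$components$component)
  dplyr::bind_cols(
    tibble::tibble(h2 = x$h2, h2_se = x$h2_se),
    tibble::as_tibble(as.list(wide)),
    tibble::tibble(loglik = x$fit$loglik, converged = x$converged,
                   niter = x$fit$niter))
}

#' @rdname mmimpute-tidiers
#' @method tidy reml_fit
#' @export
tidy.reml_fit <- function(x, ...) {
  t <- length(x$Se)
  idx <- which(lower.tri(x$Sg, diag = TRUE), arr.ind = TRUE)
  dplyr::bind_rows(
    tibble::tibble(component = ifelse(idx[, 1] == idx[, 2],
                                      paste0("sigma2_g", idx[, 1]),
                                      paste0("sigma_g", idx[, 2], idx[, 1])),
                   estimate = x$Sg[idx]),
    tibble::tibble(component = paste0("sigma2_e", seq_len(t)),
                   estimate = x$Se))
}

#' @rdname mmimpute-tidiers
#' @method glance reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, converged = x$converged,
                 boundary = x$boundary, identifiable = x$identifiable,
                 niter = x$niter)
}

#' @rdname mmimpute-tidiers
#' @method tidy vc_fit
#' @export
tidy.vc_fit <- function(x, ...) {
  tibble::tibble(component = names(x$sigma2), estimate = unname(x$sigma2))
}

#' @rdname mmimpute-tidiers
#' @method glance vc_fit
#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, converged = x$converged,
                 boundary = x$boundary, niter = x$niter)
}

#' @rdname mmimpute-tidiers
#' @method tidy imputation_result
#' @export
tidy.imputation_result <- function(x, ...) x$imputed

#' @rdname mmimpute-tidiers
#' @method glance imputation_result
#' @export
glance.imputation_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_imputed = nrow(x$imputed),
                 het = heterozygosity_proportion(x$geno),
                 mean_dosage = mean(x$imputed$dosage))
}

#' Plot an imputation result
#'
#' Histogram of the continuous dosages assigned to imputed cells, coloured
#' by the rounded ordinal call — a quick view of how confidently the
#' imputer separates the three genotype classes.
#'
#' @param object An `imputation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot imputation_result
#' @export
autoplot.imputation_result <- function(object, ...) {
  df <- object$imputed
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dosage,
                                   fill = factor(.data$call))) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::labs(x = "imputed dosage", y = "cells",
                  fill = "rounded call",
                  title = paste0("Imputed dosages (", object$method, ")")) +
    ggplot2::theme_minimal()
}

#' Plot a method-comparison quality report
#'
#' Bar charts of the post-imputation quality parameters (accuracy,
#' heterozygosity, repeated markers, and heritability / prediction accuracy
#' when available) by method and masking rate.
#'
#' @param object A `quality_report` from [compare_methods()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot quality_report
#' @export
autoplot.quality_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::any_of(c("accuracy", "het", "repeated_markers", "h2",
                    "prediction_accuracy")),
    names_to = "metric", values_to = "value")
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value,
                                     fill = factor(.data$rate))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(fill = "missing rate", y = NULL,
                  title = "Post-imputation quality by method") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
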