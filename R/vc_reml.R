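#' Specify a univariate variance-component model
#'
#' Sets up `y = X beta + sum_r Z_r u_r + e` with independent random terms
#' `u_r ~ N(0, K_r sigma2_r)` and i.i.d. residuals — the workhorse behind
#' intra-class-correlation heritability (additive kernel + environment +
#' optional controls) and ridge-type GBLUP.
#'
#' Each random term is either a factor/character vector of length `N`
#' (identity covariance over its levels) or a list with `factor` (length-`N`
#' grouping) and `kernel` (covariance over the factor levels; its
#' row/colnames define the levels, so kernel levels without records still get
#' predictions).
#'
#' @param y Numeric response vector.
#' @param random Named list of random terms (see above).
#' @param X Fixed-effect design matrix; default a single intercept.
#' @return An object of class `vc_spec`.
#' @export
vc_model <- function(y, random, X = NULL) {
  y <- as.numeric(y)
  N <- length(y)
  if (is.null(X)) X <- matrix(1, N, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  stopifnot(nrow(X) == N, length(random) >= 1)
  if (is.null(names(random)) || any(names(random) == "")) {
    stop("random terms must be named", call. = FALSE)
  }
  terms <- purrr::imap(random, function(term, nm) {
    if (!is.list(term)) term <- list(factor = term, kernel = NULL)
    f <- as.character(term$factor)
    stopifnot(length(f) == N)
    K <- term$kernel
    if (is.null(K)) {
      levels <- sort(unique(f))
      Kinv <- NULL
      ldK <- 0
    } else {
      K <- as.matrix(K)
      levels <- rownames(K)
      if (is.null(levels)) stop("kernel for term '", nm,
                                "' needs row/col names", call. = FALSE)
      missing_lv <- setdiff(unique(f), levels)
      if (length(missing_lv)) {
        stop("term '", nm, "': levels absent from kernel: ",
             paste(utils::head(missing_lv, 5), collapse = ", "),
             call. = FALSE)
      }
      ch <- chol(K + diag(1e-8, nrow(K)))
      Kinv <- chol2inv(ch)
      ldK <- 2 * sum(log(diag(ch)))
    }
    q <- length(levels)
    Z <- matrix(0, N, q, dimnames = list(NULL, levels))
    Z[cbind(seq_len(N), match(f, levels))] <- 1
    list(name = nm, Z = Z, K = K, Kinv = Kinv, ldK = ldK, q = q,
         levels = levels)
  })
  W <- cbind(X, do.call(cbind, purrr::map(terms, "Z")))
  p <- ncol(X)
  offsets <- cumsum(c(p, purrr::map_dbl(terms, "q")))
  idx <- purrr::map2(utils::head(offsets, -1), purrr::map(terms, "q"),
                     function(o, q) o + seq_len(q))
  structure(list(y = y, N = N, X = X, p = p, terms = terms, W = W,
                 WtW = crossprod(W), Wty = crossprod(W, y)[, 1],
                 yty = sum(y^2), idx = idx),
            class = "vc_spec")
}

# one Henderson-MME evaluation at fixed components
.vc_fit <- function(spec, s2, se, need_inv = TRUE) {
  dim_c <- ncol(spec$W)
  C <- spec$WtW / se
  for (r in seq_along(spec$terms)) {
    ir <- spec$idx[[r]]
    if (is.null(spec$terms[[r]]$Kinv)) {
      C[cbind(ir, ir)] <- C[cbind(ir, ir)] + 1 / s2[r]
    } else {
      C[ir, ir] <- C[ir, ir] + spec$terms[[r]]$Kinv / s2[r]
    }
  }
  rhs <- spec$Wty / se
  chC <- tryCatch(chol(C), error = function(e)
    chol(C + diag(1e-8 * mean(diag(C)), dim_c)))
  theta <- backsolve(chC, backsolve(chC, rhs, transpose = TRUE))
  ldC <- 2 * sum(log(diag(chC)))
  yPy <- spec$yty / se - sum(theta * rhs)
  ldG <- sum(vapply(seq_along(spec$terms), function(r) {
    spec$terms[[r]]$q * log(s2[r]) + spec$terms[[r]]$ldK
  }, numeric(1)))
  ll <- -0.5 * (spec$N * log(se) + ldG + ldC + yPy)
  out <- list(s2 = s2, se = se, theta = theta, ll = ll,
              beta = theta[seq_len(spec$p)],
              u = purrr::map2(spec$idx, spec$terms, function(ir, tm) {
                stats::setNames(theta[ir], tm$levels)
              }))
  out$resid <- spec$y - spec$W %*% theta
  if (need_inv) {
    Cinv <- chol2inv(chC)
    out$Cinv <- Cinv
    out$Tr <- vapply(seq_along(spec$terms), function(r) {
      ir <- spec$idx[[r]]
      if (is.null(spec$terms[[r]]$Kinv)) sum(Cinv[cbind(ir, ir)])
      else sum(Cinv[ir, ir] * spec$terms[[r]]$Kinv)
    }, numeric(1))
  }
  out
}

#' REML for univariate variance-component models
#'
#' EM warm-up plus average-information Newton steps with EM fallback, as in
#' [reml_estimate()], for [vc_model()] specifications.
#'
#' @param spec A [vc_spec][vc_model()].
#' @param tol Relative parameter-change convergence criterion (use `1e-11`
#'   for strict variance-component work).
#' @param max_iter Iteration cap.
#' @param n_em Initial pure-EM iterations.
#' @param init Optional numeric vector of starting values,
#'   `c(sigma2_terms, sigma2_residual)`.
#' @return A list of class `vc_fit`: `sigma2` (named vector of components
#'   including `residual`), `beta`, `u` (named list of BLUPs per term),
#'   `loglik`, `converged`, `boundary`, `trace`, `ai`.
#' @export
reml_vc <- function(spec, tol = 1e-8, max_iter = 200, n_em = 3,
                    init = NULL) {
  stopifnot(inherits(spec, "vc_spec"))
  R <- length(spec$terms)
  vy <- stats::var(spec$y)
  floor_v <- 1e-9 * max(vy, 1e-12)
  if (is.null(init)) {
    s2 <- rep(vy / (R + 1), R)
    se <- vy / (R + 1)
  } else {
    s2 <- init[seq_len(R)]
    se <- init[R + 1]
  }
  boundary <- FALSE
  project <- function(th) {
    out <- pmax(th, floor_v)
    if (any(out != th)) boundary <<- TRUE
    out
  }
  qs <- purrr::map_dbl(spec$terms, "q")
  em_step <- function(fit) {
    s2n <- vapply(seq_len(R), function(r) {
      ur <- fit$u[[r]]
      uku <- if (is.null(spec$terms[[r]]$Kinv)) sum(ur^2)
      else drop(crossprod(ur, spec$terms[[r]]$Kinv %*% ur))
      (uku + fit$Tr[r]) / qs[r]
    }, numeric(1))
    sen <- (sum(fit$resid^2) +
              fit$se * (ncol(spec$W) - sum(fit$Tr / fit$s2))) / spec$N
    c(s2n, sen)
  }
  ai_step <- function(fit, return_ai = FALSE) {
    Py <- fit$resid / fit$se
    Fs <- purrr::map(seq_len(R), function(r) {
      Zr <- spec$terms[[r]]$Z
      v <- crossprod(Zr, Py)[, 1]
      if (!is.null(spec$terms[[r]]$K)) v <- spec$terms[[r]]$K %*% v
      Zr %*% v
    })
    Fs[[R + 1]] <- Py
    Fmat <- do.call(cbind, Fs)
    RHS <- crossprod(spec$W, Fmat) / fit$se
    AI <- 0.5 * (crossprod(Fmat) / fit$se -
                   crossprod(RHS, fit$Cinv %*% RHS))
    score <- numeric(R + 1)
    for (r in seq_len(R)) {
      trPV <- qs[r] / fit$s2[r] - fit$Tr[r] / fit$s2[r]^2
      score[r] <- -0.5 * (trPV - sum(Py * Fs[[r]]))
    }
    trP <- spec$N / fit$se -
      (ncol(spec$W) - sum(fit$Tr / fit$s2)) / fit$se
    score[R + 1] <- -0.5 * (trP - sum(Py^2))
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    out <- if (is.null(step)) NULL else c(fit$s2, fit$se) + step
    if (return_ai) list(proposal = out, AI = AI, score = score)
    else list(proposal = out)
  }
  fit <- .vc_fit(spec, s2, se)
  trace <- list()
  converged <- FALSE
  niter <- 0
  ai_rejects <- 0
  stall <- 0
  for (it in seq_len(max_iter)) {
    niter <- it
    trace[[it]] <- tibble::tibble(iter = it, loglik = fit$ll)
    th_old <- c(fit$s2, fit$se)
    em <- project(em_step(fit))
    th_new <- em
    used_ai <- FALSE
    if (it > n_em && ai_rejects < 3) {
      prop <- ai_step(fit)$proposal
      if (!is.null(prop)) {
        th_new <- project(prop)
        used_ai <- TRUE
      }
    }
    new_fit <- .vc_fit(spec, th_new[seq_len(R)], th_new[R + 1])
    if (used_ai && new_fit$ll < fit$ll - 1e-10 * abs(fit$ll)) {
      accepted <- FALSE
      for (frac in c(0.5, 0.25)) {
        th_half <- project(th_old + frac * (th_new - th_old))
        cand <- .vc_fit(spec, th_half[seq_len(R)], th_half[R + 1])
        if (cand$ll >= fit$ll - 1e-10 * abs(fit$ll)) {
          th_new <- th_half
          new_fit <- cand
          accepted <- TRUE
          break
        }
      }
      if (!accepted) {
        ai_rejects <- ai_rejects + 1
        th_new <- em
        new_fit <- .vc_fit(spec, th_new[seq_len(R)], th_new[R + 1])
      } else {
        ai_rejects <- 0
      }
    } else if (used_ai) {
      ai_rejects <- 0
    }
    delta <- sqrt(sum((th_new - th_old)^2)) / sqrt(sum(th_old^2) + 1e-300)
    if (abs(new_fit$ll - fit$ll) < 100 * tol * (1 + abs(fit$ll))) {
      stall <- stall + 1
    } else {
      stall <- 0
    }
    fit <- new_fit
    if (delta < tol || stall >= 3) {
      converged <- TRUE
      break
    }
  }
  ai_final <- tryCatch(ai_step(fit, return_ai = TRUE)$AI,
                       error = function(e) NULL)
  sigma2 <- stats::setNames(c(fit$s2, fit$se),
                            c(names(spec$terms), "residual"))
  structure(list(sigma2 = sigma2, beta = fit$beta,
                 u = stats::setNames(fit$u, names(spec$terms)),
                 loglik = fit$ll, converged = converged,
                 boundary = boundary, trace = dplyr::bind_rows(trace),
                 niter = niter, ai = ai_final),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("<vc_fit> logLik", format(x$loglik), "|",
      if (x$converged) "converged" else "NOT converged",
      "in", x$niter, "iterations\n")
  print(x$sigma2)
  invisible(x)
}
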