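#' Specify a (multi)trait mixed model with a relationship kernel
#'
#' Sets up the model `Y = 1 mu + Z gamma + e` for `t` response columns on the
#' same `n` individuals, with `Var(vec(gamma)) = Sigma_g (x) K` for a
#' relationship kernel `K` (pedigree `A`, genomic `G`, or identity) and a
#' *diagonal* residual block `Sigma_e` (no residual covariance between
#' traits). Missing responses are handled by record omission: their rows drop
#' out of the data vector while their random effects remain predictable
#' through the kernel.
#'
#' @param Y Numeric matrix `n x t` (`t` in 1..3 for the imputation windows;
#'   any small `t` is accepted). `NA` marks missing responses.
#' @param kernel `n x n` relationship matrix; `NULL` for identity.
#' @param kernel_inv,kernel_logdet Optional precomputed inverse and
#'   log-determinant of `kernel` (reused across sliding windows).
#' @return An object of class `mm_spec`.
#' @seealso [reml_estimate()], [solve_mme()]
#' @export
mm_model <- function(Y, kernel = NULL, kernel_inv = NULL,
                     kernel_logdet = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  t <- ncol(Y)
  if (is.null(kernel)) {
    kernel <- diag(n)
    kernel_inv <- diag(n)
    kernel_logdet <- 0
  }
  stopifnot(nrow(kernel) == n, ncol(kernel) == n)
  if (is.null(kernel_inv)) {
    ch <- tryCatch(chol(kernel), error = function(e)
      chol(kernel + diag(1e-8, n)))
    kernel_inv <- chol2inv(ch)
    kernel_logdet <- 2 * sum(log(diag(ch)))
  }
  obs <- lapply(seq_len(t), function(a) which(!is.na(Y[, a])))
  if (any(lengths(obs) == 0)) {
    stop("each trait needs at least one non-missing response", call. = FALSE)
  }
  d <- lapply(obs, function(o) {
    v <- numeric(n)
    v[o] <- 1
    v
  })
  structure(list(
    Y = Y, n = n, t = t, obs = obs, d = d,
    y = lapply(seq_len(t), function(a) Y[obs[[a]], a]),
    K = kernel, Kinv = kernel_inv, ldK = kernel_logdet,
    identity_kernel = .is_identity(kernel)
  ), class = "mm_spec")
}

# u-block column indices for trait a in the MME layout [mu_1..mu_t | u]
.ucols <- function(spec, a) spec$t + (a - 1L) * spec$n + seq_len(spec$n)

# Build and solve Henderson's mixed-model equations at fixed (Sg, Se), and
# return the per-iteration quantities REML needs. C is the full coefficient
# matrix; Cinv its inverse (needed for EM/AI trace terms and PEV).
.mme_fit <- function(spec, Sg, Se, need_inv = TRUE) {
  n <- spec$n
  t <- spec$t
  Sg <- as.matrix(Sg)
  chSg <- tryCatch(chol(Sg), error = function(e) NULL)
  if (is.null(chSg)) {
    Sg <- .psd_clamp(Sg)
    chSg <- chol(Sg)
  }
  Si <- chol2inv(chSg)
  ldSg <- 2 * sum(log(diag(chSg)))
  dim_c <- t + n * t
  C <- matrix(0, dim_c, dim_c)
  rhs <- numeric(dim_c)
  for (a in seq_len(t)) {
    ua <- .ucols(spec, a)
    na <- length(spec$obs[[a]])
    C[a, a] <- na / Se[a]
    C[a, ua] <- spec$d[[a]] / Se[a]
    C[ua, a] <- spec$d[[a]] / Se[a]
    for (b in seq_len(t)) {
      ub <- .ucols(spec, b)
      blk <- Si[a, b] * spec$Kinv
      if (a == b) {
        blk <- blk + diag(spec$d[[a]] / Se[a], n)
        C[ua, ub] <- C[ua, ub] + blk
      } else {
        C[ua, ub] <- blk
      }
    }
    rhs[a] <- sum(spec$y[[a]]) / Se[a]
    rhs[ua][spec$obs[[a]]] <- spec$y[[a]] / Se[a]
  }
  chC <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(chC)) {
    chC <- chol(C + diag(1e-8 * mean(diag(C)), dim_c))
  }
  theta <- backsolve(chC, backsolve(chC, rhs, transpose = TRUE))
  ldC <- 2 * sum(log(diag(chC)))
  mu <- theta[seq_len(t)]
  U <- matrix(theta[-seq_len(t)], n, t)
  yPy <- sum(vapply(seq_len(t), function(a) sum(spec$y[[a]]^2) / Se[a],
                    numeric(1))) - sum(theta * rhs)
  ll <- -0.5 * (sum(lengths(spec$obs) * log(Se)) + n * ldSg + t * spec$ldK +
                  ldC + yPy)
  out <- list(Sg = Sg, Se = Se, Si = Si, mu = mu, U = U, ll = ll,
              theta = theta, rhs = rhs)
  out$e <- lapply(seq_len(t), function(a) {
    spec$y[[a]] - mu[a] - U[spec$obs[[a]], a]
  })
  if (need_inv) {
    Cinv <- chol2inv(chC)
    out$Cinv <- Cinv
    # T[a,b] = tr(Kinv %*% Cuu_ab); trW[a] = tr(Cinv W_a' W_a)
    Tm <- matrix(0, t, t)
    trW <- numeric(t)
    for (a in seq_len(t)) {
      ua <- .ucols(spec, a)
      for (b in seq_len(t)) {
        Tm[a, b] <- sum(Cinv[ua, .ucols(spec, b)] * spec$Kinv)
      }
      oa <- spec$obs[[a]]
      ui <- ua[oa]
      trW[a] <- length(oa) * Cinv[a, a] + 2 * sum(Cinv[a, ui]) +
        sum(Cinv[cbind(ui, ui)])
    }
    out$Tm <- Tm
    out$trW <- trW
    out$UKU <- crossprod(U, spec$Kinv %*% U)
  }
  out
}

# clamp a symmetric matrix to the PSD cone (small positive floor on
# eigenvalues so the result stays invertible)
.psd_clamp <- function(S, rel = 1e-8) {
  eg <- eigen(S, symmetric = TRUE)
  floor_val <- rel * max(abs(eg$values), 1e-12)
  vals <- pmax(eg$values, floor_val)
  out <- eg$vectors %*% (vals * t(eg$vectors))
  (out + t(out)) / 2
}

# parameter vector <-> (Sg, Se); vech order (1,1),(2,1),...,(t,t)
.vc_pack <- function(Sg, Se) {
  t <- length(Se)
  c(Sg[lower.tri(Sg, diag = TRUE)], Se)
}

.vc_unpack <- function(th, t) {
  Sg <- matrix(0, t, t)
  Sg[lower.tri(Sg, diag = TRUE)] <- th[seq_len(t * (t + 1) / 2)]
  Sg <- Sg + t(Sg) - diag(diag(Sg), t)
  list(Sg = Sg, Se = th[t * (t + 1) / 2 + seq_len(t)])
}

# EM-REML update from a fitted iteration (guaranteed-ascent step)
.em_step <- function(spec, fit) {
  n <- spec$n
  Sg_new <- (fit$UKU + fit$Tm) / n
  Sg_new <- (Sg_new + t(Sg_new)) / 2
  Se_new <- vapply(seq_len(spec$t), function(a) {
    (sum(fit$e[[a]]^2) + fit$trW[a]) / length(spec$obs[[a]])
  }, numeric(1))
  list(Sg = Sg_new, Se = Se_new)
}

# Average-information step: Newton update using the AI approximation to the
# expected information, with exact REML scores via MME trace identities.
.ai_step <- function(spec, fit, return_ai = FALSE) {
  n <- spec$n
  t <- spec$t
  Se <- fit$Se
  Si <- fit$Si
  pairs <- which(lower.tri(matrix(0, t, t), diag = TRUE), arr.ind = TRUE)
  npar <- nrow(pairs) + t
  Wm <- matrix(0, n, t)
  for (a in seq_len(t)) Wm[spec$obs[[a]], a] <- fit$e[[a]] / Se[a]
  KW <- spec$K %*% Wm
  Fs <- vector("list", npar)
  for (p in seq_len(nrow(pairs))) {
    a <- pairs[p, 2]  # col index (a <= b)
    b <- pairs[p, 1]
    Fp <- matrix(0, n, t)
    Fp[, a] <- Fp[, a] + KW[, b]
    if (a != b) Fp[, b] <- Fp[, b] + KW[, a]
    Fs[[p]] <- Fp * do.call(cbind, spec$d)
  }
  for (a in seq_len(t)) {
    Fp <- matrix(0, n, t)
    Fp[, a] <- Wm[, a]
    Fs[[nrow(pairs) + a]] <- Fp
  }
  # rhs vectors W' R^-1 f_p and raw cross-products f_p' R^-1 f_q
  dim_c <- t + n * t
  RHS <- matrix(0, dim_c, npar)
  for (p in seq_len(npar)) {
    for (a in seq_len(t)) {
      RHS[a, p] <- sum(Fs[[p]][spec$obs[[a]], a]) / Se[a]
      RHS[.ucols(spec, a), p] <- Fs[[p]][, a] * spec$d[[a]] / Se[a]
    }
  }
  raw <- matrix(0, npar, npar)
  for (p in seq_len(npar)) {
    for (q in p:npar) {
      v <- sum(vapply(seq_len(t), function(a) {
        sum(Fs[[p]][spec$obs[[a]], a] * Fs[[q]][spec$obs[[a]], a]) / Se[a]
      }, numeric(1)))
      raw[p, q] <- v
      raw[q, p] <- v
    }
  }
  AI <- 0.5 * (raw - crossprod(RHS, fit$Cinv %*% RHS))
  # scores
  tKM <- n * Si - Si %*% fit$Tm %*% Si
  score <- numeric(npar)
  for (p in seq_len(nrow(pairs))) {
    a <- pairs[p, 2]
    b <- pairs[p, 1]
    trPV <- if (a == b) tKM[a, a] else 2 * tKM[a, b]
    yPVPy <- sum(vapply(seq_len(t), function(s) {
      sum(Wm[spec$obs[[s]], s] * Fs[[p]][spec$obs[[s]], s])
    }, numeric(1)))
    score[p] <- -0.5 * (trPV - yPVPy)
  }
  for (a in seq_len(t)) {
    na <- length(spec$obs[[a]])
    trPV <- na / Se[a] - fit$trW[a] / Se[a]^2
    yPVPy <- sum(Wm[spec$obs[[a]], a]^2)
    score[nrow(pairs) + a] <- -0.5 * (trPV - yPVPy)
  }
  step <- tryCatch(solve(AI, score), error = function(e) NULL)
  th <- .vc_pack(fit$Sg, Se)
  out <- if (is.null(step)) NULL else .vc_unpack(th + step, t)
  if (return_ai) list(proposal = out, AI = AI, score = score) else
    list(proposal = out)
}

#' REML estimation of the variance components
#'
#' Estimates the genetic covariance block `Sigma_g` (full symmetric) and the
#' diagonal residual block `Sigma_e` of an [mm_model()] by restricted maximum
#' likelihood: expectation-maximisation warm-up (guaranteed likelihood
#' ascent) followed by average-information Newton steps, falling back to EM
#' whenever an AI proposal would decrease the restricted likelihood or leave
#' the parameter space. Convergence is declared when the relative norm of the
#' parameter change falls below `tol`.
#'
#' @param spec An [mm_model()] specification.
#' @param tol Relative parameter-change convergence criterion. The default
#'   `1e-8` suits the imputation sliding window; pass `1e-11` to reproduce
#'   strict variance-component estimation.
#' @param max_iter Iteration cap; on hitting it the best estimate is
#'   returned with `converged = FALSE`.
#' @param init Optional list with starting `Sg` and `Se`.
#' @param n_em Number of initial pure-EM iterations.
#' @param method `"ai"` (default) or `"em"` for pure EM-REML.
#' @return A list of class `reml_fit`: `Sg`, `Se`, `loglik`, `converged`,
#'   `boundary` (a component was floored or clamped), `identifiable`
#'   (`FALSE` when the kernel is the identity, which confounds gamma and e),
#'   `trace` (per-iteration tibble), `niter`, and `ai` (the average
#'   information matrix at the optimum, when available).
#' @export
reml_estimate <- function(spec, tol = 1e-8, max_iter = 200, init = NULL,
                          n_em = 3, method = c("ai", "em")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "mm_spec"))
  t <- spec$t
  if (spec$n < t + 2) stop("need n >= t + 2 individuals", call. = FALSE)
  C0 <- stats::cov(spec$Y, use = "pairwise.complete.obs")
  C0[is.na(C0)] <- 0
  v <- pmax(diag(as.matrix(C0)), 1e-12)
  se_floor <- 1e-9 * pmax(v, mean(v))
  if (is.null(init)) {
    Sg <- .psd_clamp(as.matrix(C0) / 2)
    Se <- v / 2
  } else {
    Sg <- as.matrix(init$Sg)
    Se <- pmax(init$Se, se_floor)
  }
  boundary <- FALSE
  project <- function(Sg, Se) {
    Se2 <- pmax(Se, se_floor)
    eg <- eigen(Sg, symmetric = TRUE)
    if (min(eg$values) < 1e-10 * max(abs(eg$values), 1e-12)) {
      Sg <- .psd_clamp(Sg)
      boundary <<- TRUE
    }
    if (any(Se2 != Se)) boundary <<- TRUE
    list(Sg = Sg, Se = Se2)
  }
  trace <- list()
  fit <- .mme_fit(spec, Sg, Se)
  converged <- FALSE
  niter <- 0
  pending_em <- NULL # fallback params if the last (AI) proposal regresses
  ai_rejects <- 0
  stall <- 0
  for (it in seq_len(max_iter)) {
    niter <- it
    pending_em <- NULL
    th_old <- .vc_pack(fit$Sg, fit$Se)
    em <- .em_step(spec, fit)
    use_ai <- method == "ai" && it > n_em && ai_rejects < 3
    nxt <- NULL
    if (use_ai) {
      ai <- .ai_step(spec, fit)
      if (!is.null(ai$proposal)) {
        pr <- project(ai$proposal$Sg, ai$proposal$Se)
        nxt <- pr
        pending_em <- em
      }
    }
    if (is.null(nxt)) nxt <- project(em$Sg, em$Se)
    th_new <- .vc_pack(nxt$Sg, nxt$Se)
    delta <- sqrt(sum((th_new - th_old)^2)) /
      sqrt(sum(th_old^2) + 1e-300)
    new_fit <- .mme_fit(spec, nxt$Sg, nxt$Se)
    if (!is.null(pending_em) && new_fit$ll < fit$ll - 1e-10 * abs(fit$ll)) {
      # AI overshoot: try shortened steps, then fall back to EM
      accepted <- FALSE
      for (frac in c(0.5, 0.25)) {
        uh <- .vc_unpack(th_old + frac * (th_new - th_old), t)
        pr <- project(uh$Sg, uh$Se)
        cand <- .mme_fit(spec, pr$Sg, pr$Se)
        if (cand$ll >= fit$ll - 1e-10 * abs(fit$ll)) {
          new_fit <- cand
          th_new <- .vc_pack(cand$Sg, cand$Se)
          accepted <- TRUE
          break
        }
      }
      if (!accepted) {
        ai_rejects <- ai_rejects + 1
        pr <- project(pending_em$Sg, pending_em$Se)
        new_fit <- .mme_fit(spec, pr$Sg, pr$Se)
        th_new <- .vc_pack(new_fit$Sg, new_fit$Se)
        pending_em <- NULL
      } else {
        ai_rejects <- 0
      }
      delta <- sqrt(sum((th_new - th_old)^2)) /
        sqrt(sum(th_old^2) + 1e-300)
    } else if (!is.null(pending_em)) {
      ai_rejects <- 0
    }
    trace[[it]] <- tibble::tibble(
      iter = it, loglik = fit$ll, delta = delta,
      step = if (is.null(pending_em) && use_ai) "em" else
        if (use_ai) "ai" else "em")
    # likelihood stagnation: a flat boundary ridge where the parameters
    # still drift; predictions no longer change, so stop
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
  ai_final <- tryCatch(.ai_step(spec, fit, return_ai = TRUE)$AI,
                       error = function(e) NULL)
  structure(list(
    Sg = fit$Sg, Se = fit$Se, loglik = fit$ll, converged = converged,
    boundary = boundary, identifiable = !spec$identity_kernel,
    trace = dplyr::bind_rows(trace), niter = niter, ai = ai_final
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit> logLik", format(x$loglik), "|",
      if (x$converged) "converged" else "NOT converged",
      "in", x$niter, "iterations",
      if (x$boundary) "(boundary)", "\n")
  cat("Sigma_g:\n")
  print(x$Sg)
  cat("Sigma_e (diagonal):", format(x$Se), "\n")
  invisible(x)
}

#' Solve Henderson's mixed-model equations at fixed variance components
#'
#' Returns the BLUE of the per-trait intercepts and the BLUP (empirical
#' Bayes) predictions of the individual effects, for all individuals covered
#' by the kernel — including those with missing responses, whose predictions
#' borrow information through the kernel and the genetic covariances.
#'
#' @param spec An [mm_model()].
#' @param vc A list (or `reml_fit`) with `Sg` (t x t genetic covariance) and
#'   `Se` (length-t residual variances).
#' @param pev Also return prediction error variances (diagonal of the
#'   inverse coefficient matrix)?
#' @return A list of class `blup_solution` with `mu` (t), `u` (n x t matrix
#'   of BLUPs), `fitted` (`mu + u`), `loglik`, and optionally `pev`.
#' @export
solve_mme <- function(spec, vc, pev = FALSE) {
  stopifnot(inherits(spec, "mm_spec"))
  fit <- .mme_fit(spec, vc$Sg, vc$Se, need_inv = pev)
  out <- list(mu = fit$mu, u = fit$U,
              fitted = sweep(fit$U, 2, fit$mu, "+"),
              loglik = fit$ll)
  if (pev) {
    out$pev <- vapply(seq_len(spec$t), function(a) {
      ua <- .ucols(spec, a)
      fit$Cinv[cbind(ua, ua)]
    }, numeric(spec$n))
  }
  structure(out, class = "blup_solution")
}

#' Restricted log-likelihood at given variance components
#'
#' @inheritParams solve_mme
#' @return The restricted log-likelihood (up to the usual additive constant).
#' @export
reml_loglik <- function(spec, vc) {
  .mme_fit(spec, vc$Sg, vc$Se, need_inv = FALSE)$ll
}

#' Profile the restricted likelihood over one variance component
#'
#' Evaluates the restricted log-likelihood on a grid for one component,
#' holding the others fixed — a diagnostic for convergence and boundary
#' issues.
#'
#' @inheritParams solve_mme
#' @param component `"genetic"` or `"residual"`.
#' @param index For `"genetic"`, `c(a, b)` into `Sg`; for `"residual"`, the
#'   trait index.
#' @param grid Numeric vector of component values to evaluate.
#' @return A tibble with `value` and `loglik`.
#' @export
reml_profile_likelihood <- function(spec, vc, component = c("genetic",
                                                            "residual"),
                                    index = c(1, 1), grid) {
  component <- match.arg(component)
  purrr::map_dfr(grid, function(g) {
    Sg <- as.matrix(vc$Sg)
    Se <- vc$Se
    if (component == "genetic") {
      Sg[index[1], index[2]] <- g
      Sg[index[2], index[1]] <- g
    } else {
      Se[index[1]] <- g
    }
    ll <- tryCatch(.mme_fit(spec, Sg, Se, need_inv = FALSE)$ll,
                   error = function(e) NA_real_)
    tibble::tibble(value = g, loglik = ll)
  })
}
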