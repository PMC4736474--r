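random_mm_instance <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(5:30, 1)
    t <- sample(1:3, 1)
    L <- matrix(rnorm(n * n), n)
    K <- crossprod(L) / n + diag(n)
    Lg <- matrix(rnorm(t * t), t)
    Sg <- crossprod(Lg) / t + diag(t) * 0.5
    Se <- runif(t, 0.3, 1.5)
    Y <- matrix(rnorm(n * t), n, t)
    for (a in seq_len(t)) {
      k <- sample(0:(n - 3), 1)
      if (k > 0) Y[sample(n, k), a] <- NA
    }
    list(Y = Y, K = K, Sg = Sg, Se = Se)
  })
}

test_that("solve_mme agrees with explicit GLS inversion on random
           instances", {
  for (seed in 1:25) {
    inst <- random_mm_instance(seed)
    spec <- mm_model(inst$Y, kernel = inst$K)
    sol <- solve_mme(spec, list(Sg = inst$Sg, Se = inst$Se))
    or <- gls_oracle(inst$Y, inst$K, inst$Sg, inst$Se)
    expect_lt(max(abs(sol$mu - or$beta)), 1e-8)
    expect_lt(max(abs(sol$u - or$U)), 1e-8)
    expect_lt(abs(sol$loglik - or$loglik), 1e-6)
  }
})

test_that("infinite shrinkage sends BLUPs to zero and the BLUE to the
           trait mean", {
  withr::with_seed(1, {
    y <- rnorm(20, mean = 5)
  })
  spec <- mm_model(matrix(y, ncol = 1), kernel = diag(20) + 0.1)
  sol <- solve_mme(spec, list(Sg = matrix(1e-10), Se = 1))
  expect_lt(max(abs(sol$u)), 1e-6)
  # mu is then the GLS mean, which for near-zero Sg is the sample mean
  expect_equal(sol$mu, mean(y), tolerance = 1e-4)
})

test_that("a constant response gives mu = c and zero BLUPs", {
  spec <- mm_model(matrix(3, 15, 1), kernel = diag(15) + 0.2)
  sol <- solve_mme(spec, list(Sg = matrix(0.5), Se = 0.5))
  expect_equal(sol$mu, 3, tolerance = 1e-10)
  expect_lt(max(abs(sol$u)), 1e-10)
})

test_that("n = 4 parent-offspring univariate BLUP matches the closed-form
           conditional expectation", {
  # pedigree: two founders, offspring, grand-offspring
  ped <- build_pedigree(tibble::tibble(
    id = c("f1", "f2", "o", "g"),
    parent1 = c(NA, NA, "f1", "o"),
    parent2 = c(NA, NA, "f2", NA),
    selfing_generations = 0))
  A <- a_matrix(ped)
  y <- c(1.2, -0.5, 0.9, NA)
  Sg <- matrix(1)
  Se <- 0.5
  spec <- mm_model(matrix(y, ncol = 1), kernel = A)
  sol <- solve_mme(spec, list(Sg = Sg, Se = Se))
  # direct conditional-expectation oracle on the observed 3-vector
  obs <- 1:3
  V <- A[obs, obs] + diag(Se, 3)
  X <- matrix(1, 3, 1)
  Vi <- solve(V)
  mu <- drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y[obs]))
  u <- drop(A[, obs] %*% Vi %*% (y[obs] - mu))
  expect_equal(sol$mu, mu, tolerance = 1e-9)
  expect_equal(unname(sol$u[, 1]), unname(u), tolerance = 1e-9)
})

test_that("the restricted likelihood never decreases under EM steps", {
  for (seed in c(2, 7)) {
    inst <- random_mm_instance(seed)
    spec <- mm_model(inst$Y, kernel = inst$K)
    fit <- reml_estimate(spec, method = "em", max_iter = 40, tol = 1e-12)
    expect_true(all(diff(fit$trace$loglik) > -1e-7))
  }
})

test_that("univariate REML recovers simulated variance components", {
  # balanced half-sib-like structure, sigma2_g = sigma2_e = 1
  withr::with_seed(99, {
    n_fam <- 40
    per <- 10
    n <- n_fam * per
    fam <- rep(seq_len(n_fam), each = per)
    K <- 0.5 * outer(fam, fam, "==") + diag(n) * 0.5
    L <- chol(K)
    est <- replicate(20, {
      u <- drop(t(L) %*% rnorm(n))
      y <- 2 + u + rnorm(n)
      fit <- reml_estimate(mm_model(matrix(y, ncol = 1), kernel = K),
                           tol = 1e-8)
      c(fit$Sg[1, 1], fit$Se[1])
    })
  })
  expect_lt(abs(mean(est[1, ]) - 1), 0.15)
  expect_lt(abs(mean(est[2, ]) - 1), 0.15)
})

test_that("independent traits yield near-zero genetic cross-covariances", {
  withr::with_seed(17, {
    n_fam <- 40
    per <- 10
    n <- n_fam * per
    fam <- rep(seq_len(n_fam), each = per)
    K <- 0.5 * outer(fam, fam, "==") + diag(n) * 0.5
    L <- chol(K)
    U <- t(L) %*% matrix(rnorm(n * 3), n)   # block-diagonal truth
    Y <- U + matrix(rnorm(n * 3), n)
    fit <- reml_estimate(mm_model(Y, kernel = K), tol = 1e-8)
  })
  off <- fit$Sg[lower.tri(fit$Sg)]
  expect_lt(max(abs(off)), 0.1 * sqrt(max(diag(fit$Sg))))
})

test_that("REML estimates are invariant to shifting a trait by a
           constant", {
  inst <- random_mm_instance(12)
  spec1 <- mm_model(inst$Y, kernel = inst$K)
  Y2 <- inst$Y
  Y2[, 1] <- Y2[, 1] + 100
  spec2 <- mm_model(Y2, kernel = inst$K)
  f1 <- reml_estimate(spec1, tol = 1e-9)
  f2 <- reml_estimate(spec2, tol = 1e-9)
  expect_equal(f2$Sg, f1$Sg, tolerance = 1e-4)
  expect_equal(f2$Se, f1$Se, tolerance = 1e-4)
})

test_that("identity-kernel fits are flagged unidentifiable", {
  withr::with_seed(3, y <- rnorm(25))
  fit <- reml_estimate(mm_model(matrix(y, ncol = 1)), tol = 1e-6,
                       max_iter = 50)
  expect_false(fit$identifiable)
})

test_that("the profile likelihood peaks at the REML estimate", {
  # structured toys with an interior optimum (family kernel, clear signal)
  for (seed in c(4, 9, 21)) {
    withr::with_seed(seed, {
      n_fam <- 30
      per <- 8
      n <- n_fam * per
      fam <- rep(seq_len(n_fam), each = per)
      K <- 0.5 * outer(fam, fam, "==") + diag(n) * 0.5
      u <- drop(t(chol(K)) %*% rnorm(n))
      y <- 1 + u + rnorm(n)
    })
    spec <- mm_model(matrix(y, ncol = 1), kernel = K)
    fit <- reml_estimate(spec, tol = 1e-10, max_iter = 300)
    est <- fit$Sg[1, 1]
    grid <- seq(0.4, 2.5, length.out = 15) * est
    prof <- reml_profile_likelihood(spec, fit, "genetic", c(1, 1), grid)
    peak <- prof$value[which.max(prof$loglik)]
    # grid maximum should bracket the estimate within one grid step
    expect_lt(abs(peak - est), diff(grid)[1] + 1e-9)
    expect_lte(max(prof$loglik, na.rm = TRUE), fit$loglik + 1e-6)
    # the likelihood tails off monotonically far beyond the optimum
    tail_grid <- est * c(5, 10, 20, 40)
    tail_prof <- reml_profile_likelihood(spec, fit, "genetic", c(1, 1),
                                         tail_grid)
    expect_true(all(diff(tail_prof$loglik) < 0))
  }
})

test_that("the univariate multi-kernel engine matches a dense REML
           oracle and recovers structure", {
  withr::with_seed(5, {
    n <- 40
    ids <- paste0("i", 1:n)
    L <- matrix(rnorm(n * n), n)
    K <- crossprod(L) / n + diag(n)
    dimnames(K) <- list(ids, ids)
    env <- rep(c("e1", "e2", "e3"), length.out = 2 * n)
    who <- rep(ids, 2)
    u <- drop(t(chol(K)) %*% rnorm(n)) * 1.2
    y <- 3 + u[who] + c(e1 = 0.5, e2 = -0.5, e3 = 0)[env] +
      rnorm(2 * n, 0, 0.8)
  })
  spec <- vc_model(y, random = list(
    env = env, additive = list(factor = who, kernel = K)))
  fit <- reml_vc(spec, tol = 1e-10)
  # dense restricted-likelihood oracle at the fitted components
  Zf <- function(f, lv) {
    Z <- matrix(0, length(f), length(lv))
    Z[cbind(seq_along(f), match(f, lv))] <- 1
    Z
  }
  Ze <- Zf(env, sort(unique(env)))
  Za <- Zf(who, ids)
  V <- fit$sigma2[1] * tcrossprod(Ze) +
    fit$sigma2[2] * Za %*% K %*% t(Za) + diag(fit$sigma2[3], 2 * n)
  X <- matrix(1, 2 * n, 1)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r0 <- y - X %*% b
  ll <- -0.5 * (as.numeric(determinant(V)$modulus) +
                  as.numeric(determinant(t(X) %*% Vi %*% X)$modulus) +
                  drop(t(r0) %*% Vi %*% r0))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
  # perturbing any component can only lower the restricted likelihood
  for (i in 1:3) {
    s <- fit$sigma2
    s[i] <- s[i] * 1.1
    V2 <- s[1] * tcrossprod(Ze) + s[2] * Za %*% K %*% t(Za) +
      diag(s[3], 2 * n)
    Vi2 <- solve(V2)
    b2 <- solve(t(X) %*% Vi2 %*% X, t(X) %*% Vi2 %*% y)
    r2 <- y - X %*% b2
    ll2 <- -0.5 * (as.numeric(determinant(V2)$modulus) +
                     as.numeric(determinant(t(X) %*% Vi2 %*% X)$modulus) +
                     drop(t(r2) %*% Vi2 %*% r2))
    expect_lte(ll2, fit$loglik + 1e-8)
  }
})
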