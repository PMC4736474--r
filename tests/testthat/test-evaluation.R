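test_that("imputation accuracy counts identical masked calls", {
  gm <- geno_matrix(matrix(rep(c(0, 1, 2), 10), 5, 6))
  mask <- tibble::tibble(row = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5),
                         col = rep(1:2, each = 5))
  imp <- gm
  expect_equal(imputation_accuracy(imp, gm, mask), 1)
  imp$calls[1, 1] <- (imp$calls[1, 1] + 1) %% 3
  expect_equal(imputation_accuracy(imp, gm, mask), 0.9)
  expect_true(is.na(imputation_accuracy(imp, gm, mask[0, ])))
})

test_that("VanRaden G has the algebraic diagonals and Gram structure", {
  # all-heterozygous individual at p = 0.5: centred row is zero
  calls <- rbind(rep(1, 10), rep(0, 10), rep(2, 10))
  G <- vanraden_g(geno_matrix(calls))
  expect_equal(G[1, 1], 0)
  # homozygous-alt everywhere at p = 0.5 gives diagonal m/(2m/4) = 2
  expect_equal(G[3, 3], 2)
  withr::with_seed(4, {
    Xr <- matrix(rbinom(30 * 50, 2, 0.5), 30, 50)
  })
  Gr <- vanraden_g(geno_matrix(Xr))
  expect_equal(Gr, t(Gr))
  expect_gte(min(eigen(Gr, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_error(vanraden_g(geno_matrix(matrix(2, 4, 3))), "monomorphic")
})

test_that("pure-noise phenotypes give near-zero heritability", {
  tb <- small_nam(seed = 21, n_families = 12, ril_per_family = 15)
  A <- a_matrix(tb$pedigree)
  ph <- tb$phenotypes
  ph$value <- withr::with_seed(3, stats::rnorm(nrow(ph)))
  fit <- estimate_heritability(ph, A, tol = 1e-8)
  expect_lte(fit$h2, 0.1)
})

test_that("heritability estimation needs two environments and a covering
           kernel", {
  tb <- small_nam(seed = 22)
  A <- a_matrix(tb$pedigree)
  ph1 <- tb$phenotypes[tb$phenotypes$env == "env1", ]
  expect_error(estimate_heritability(ph1, A), "2 environments")
  ph2 <- tb$phenotypes
  ph2$id[1] <- "stranger"
  expect_error(estimate_heritability(ph2, A), "stranger")
})

test_that("heritability recovery and the environment share on simulated
           traits", {
  est <- purrr::map_dfr(1:6, function(s) {
    tb <- small_nam(seed = 100 + s, n_families = 15, ril_per_family = 12,
                    h2 = 0.4, env_var_share = 0.2)
    fit <- estimate_heritability(tb$phenotypes, a_matrix(tb$pedigree),
                                 tol = 1e-8)
    wide <- stats::setNames(fit$components$estimate,
                            fit$components$component)
    tibble::tibble(h2 = fit$h2,
                   env_share = wide["sigma2_E"] / sum(wide))
  })
  expect_lt(abs(mean(est$h2) - 0.4), 0.1)
  # environment share is noisy with few environments but unbiased-ish
  expect_lt(abs(mean(est$env_share) - 0.2), 0.15)
})

test_that("five-fold GBLUP accuracy is high for near-noiseless traits,
           null for permuted ones, and seed-stable", {
  tb <- small_nam(seed = 55, n_families = 15, ril_per_family = 12,
                  markers_per_chromosome = 25, h2 = 0.95,
                  env_var_share = 0.02)
  cv1 <- prediction_accuracy_cv(tb$geno, tb$phenotypes, seed = 7)
  cv2 <- prediction_accuracy_cv(tb$geno, tb$phenotypes, seed = 7)
  expect_identical(cv1$folds, cv2$folds)
  expect_gte(cv1$accuracy, 0.8)
  phn <- tb$phenotypes
  phn$value <- withr::with_seed(9, sample(phn$value))
  cvn <- prediction_accuracy_cv(tb$geno, phn, seed = 7)
  # permuted phenotypes either trip the low-heritability guard or leave a
  # near-zero raw correlation
  expect_true(cvn$undefined || abs(cvn$accuracy) <= 0.25)
  expect_lte(mean(abs(cvn$folds$cor)), 0.3)
})

test_that("compare_methods assembles one row per method and rate, scores
           the truth passthrough perfectly, and is reproducible", {
  tb <- small_nam(seed = 71, n_families = 8, ril_per_family = 8,
                  markers_per_chromosome = 10)
  A <- a_matrix(tb$pedigree)
  rep1 <- compare_methods(tb$geno, A = A,
                          methods = c("mode", "knn", "truth"),
                          rates = c(0.1, 0.3), seed = 5)
  expect_equal(nrow(rep1), 6)
  expect_setequal(unique(rep1$method), c("mode", "knn", "truth"))
  tr <- rep1[rep1$method == "truth", ]
  expect_true(all(tr$accuracy == 1))
  expect_equal(tr$het[1], heterozygosity_proportion(tb$geno))
  rep2 <- compare_methods(tb$geno, A = A,
                          methods = c("mode", "knn", "truth"),
                          rates = c(0.1, 0.3), seed = 5)
  expect_identical(tibble::as_tibble(rep1), tibble::as_tibble(rep2))
  expect_s3_class(ggplot2::autoplot(rep1), "ggplot")
})

test_that("a failing method is reported as a missing row without
           stopping the run", {
  tb <- small_nam(seed = 72, n_families = 4, ril_per_family = 5,
                  markers_per_chromosome = 6)
  boom <- function(gm) stop("deliberate failure")
  rep <- compare_methods(tb$geno, methods = list(mode = NULL, bad = boom),
                         rates = 0.2, seed = 1)
  expect_equal(nrow(rep), 2)
  bad_row <- rep[rep$method == "bad", ]
  expect_true(is.na(bad_row$accuracy))
  expect_match(bad_row$status, "deliberate")
})

test_that("pedigree and truth-matrix genomic kernels agree on
           heritability within 0.1 at n = 600", {
  # founders drawn independently, so realized relationships carry the
  # pedigree signal the two kernels are supposed to share
  gaps <- vapply(1:3, function(s) {
    tb <- simulate_nam(sim_config(
      n_families = 20, ril_per_family = 30, n_chromosomes = 3,
      markers_per_chromosome = 100, h2 = 0.4, founder_poly_rate = 0.5,
      seed = s))
    A <- a_matrix(tb$pedigree)
    G <- vanraden_g(tb$geno)
    abs(estimate_heritability(tb$phenotypes, A, tol = 1e-8)$h2 -
          estimate_heritability(tb$phenotypes,
                                G + diag(1e-6, nrow(G)), tol = 1e-8)$h2)
  }, numeric(1))
  expect_lte(mean(gaps), 0.1)
})

test_that("heritability fits expose tidy and glance methods", {
  tb <- small_nam(seed = 73)
  fit <- estimate_heritability(tb$phenotypes, a_matrix(tb$pedigree),
                               tol = 1e-8)
  td <- generics::tidy(fit)
  expect_true(all(c("component", "estimate") %in% names(td)))
  gl <- generics::glance(fit)
  expect_true(all(c("h2", "sigma2_A", "converged") %in% names(gl)))
  expect_equal(gl$h2, fit$h2)
})
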