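# Dense generalised-least-squares oracle for the multitrait kernel model:
# builds V over observed records explicitly and solves by direct inversion.
# Kept independent of the MME solver it checks.
gls_oracle <- function(Y, K, Sg, Se) {
  n <- nrow(Y)
  t <- ncol(Y)
  recs <- which(!is.na(Y), arr.ind = TRUE)
  recs <- recs[order(recs[, 2], recs[, 1]), , drop = FALSE]
  N <- nrow(recs)
  V <- matrix(0, N, N)
  for (p in seq_len(N)) {
    for (q in seq_len(N)) {
      i <- recs[p, 1]; a <- recs[p, 2]
      j <- recs[q, 1]; b <- recs[q, 2]
      V[p, q] <- Sg[a, b] * K[i, j] + (a == b && i == j) * Se[a]
    }
  }
  X <- matrix(0, N, t)
  X[cbind(seq_len(N), recs[, 2])] <- 1
  y <- Y[recs]
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  Cuy <- matrix(0, n * t, N)
  for (b in seq_len(t)) {
    for (j in seq_len(n)) {
      Cuy[(b - 1) * n + j, ] <- Sg[b, recs[, 2]] * K[j, recs[, 1]]
    }
  }
  u <- Cuy %*% Vi %*% r
  ll <- -0.5 * (as.numeric(determinant(V)$modulus) +
                  as.numeric(determinant(t(X) %*% Vi %*% X)$modulus) +
                  drop(t(r) %*% Vi %*% r))
  list(beta = drop(beta), U = matrix(u, n, t), loglik = ll)
}

# Random valid pedigree (founders first, offspring drawn from earlier
# individuals, occasional selfing counts) for property tests.
random_pedigree <- function(n, seed) {
  withr::with_seed(seed, {
    n_founder <- max(2, rbinom(1, n, 0.3))
    ids <- paste0("i", seq_len(n))
    p1 <- p2 <- rep(NA_character_, n)
    s <- integer(n)
    for (i in seq_len(n)) {
      if (i > n_founder) {
        pool <- ids[seq_len(i - 1)]
        p1[i] <- sample(pool, 1)
        p2[i] <- sample(pool, 1)
        s[i] <- sample(0:3, 1, prob = c(0.7, 0.1, 0.1, 0.1))
      }
    }
    build_pedigree(tibble::tibble(id = ids, parent1 = p1, parent2 = p2,
                                  selfing_generations = s))
  })
}

# Mendelian gene dropping through a non-inbred pedigree (two independently
# drawn founder alleles each, one random allele transmitted per parent).
# For this process the numerator-relationship model of gene content is exact,
# so it serves as the oracle for marker-heritability behaviour.
gene_drop_outbred <- function(ped, p_allele = 0.5, seed = 1) {
  withr::with_seed(seed, {
    recs <- ped$records
    n <- nrow(recs)
    al <- matrix(NA_real_, n, 2, dimnames = list(recs$id, NULL))
    for (i in seq_len(n)) {
      for (k in 1:2) {
        par <- recs[[paste0("parent", k)]][i]
        al[i, k] <- if (is.na(par)) rbinom(1, 1, p_allele) else
          al[par, sample(1:2, 1)]
      }
    }
    rowSums(al)
  })
}

# Small NAM bundle used across tests (cheap but structured).
small_nam <- function(seed = 1, ...) {
  args <- utils::modifyList(list(
    n_families = 6, ril_per_family = 8, n_chromosomes = 2,
    markers_per_chromosome = 12, map_length_cM = 100, seed = seed), list(...))
  simulate_nam(do.call(sim_config, args))
}
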