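#' Simulation settings for a NAM population
#'
#' Describes the emulated design: one common parent crossed to
#' `n_families` founders, each cross advanced by single-seed descent for
#' `selfing_generations` rounds of selfing (the default 4 yields F5 lines,
#' expected inbreeding 93.75%), biallelic markers on a genetic map with
#' Haldane (no-interference) recombination, an additive polygenic trait at a
#' target narrow-sense heritability, environment effects, and optional MCAR
#' missingness and genotyping-error injection.
#'
#' The default founder polymorphism rate of 1 makes every marker segregate in
#' every cross, the idealisation under which the expected F5 heterozygosity
#' is exactly 6.25% of all loci; lower it for panels where some families are
#' monomorphic at some markers.
#'
#' @param n_families Number of biparental crosses sharing the common parent.
#' @param ril_per_family Recombinant inbred lines per cross.
#' @param selfing_generations Selfing rounds after the F1 (4 = F5 RILs).
#' @param n_chromosomes,markers_per_chromosome,map_length_cM Genome layout;
#'   markers are equally spaced on each chromosome.
#' @param founder_poly_rate Probability that a founder carries the allele
#'   opposite to the common parent at a marker.
#' @param n_qtl Number of marker-QTL underlying the trait (a subset of panel
#'   markers).
#' @param h2 Target narrow-sense heritability of single-record phenotypes.
#' @param env_var_share Share of phenotypic variance due to environment;
#'   `h2 + env_var_share` must be below 1.
#' @param n_environments Environments in which each line is phenotyped.
#' @param missing_rate MCAR masking rate applied to produce the observed
#'   panel (0 = none).
#' @param genotyping_error_rate Per-cell miscall rate (0 = error-free).
#' @param seed Integer seed; the whole bundle is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 20, ril_per_family = 30,
                       selfing_generations = 4, n_chromosomes = 3,
                       markers_per_chromosome = 100, map_length_cM = 120,
                       founder_poly_rate = 1, n_qtl = 40, h2 = 0.4,
                       env_var_share = 0.2, n_environments = 4,
                       missing_rate = 0, genotyping_error_rate = 0,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_families >= 1, ril_per_family >= 1, selfing_generations >= 0,
            n_chromosomes >= 1, markers_per_chromosome >= 1,
            map_length_cM >= 0, founder_poly_rate >= 0,
            founder_poly_rate <= 1, n_qtl >= 1, h2 > 0, h2 <= 1,
            env_var_share >= 0, missing_rate >= 0, missing_rate < 1,
            genotyping_error_rate >= 0, genotyping_error_rate < 1,
            n_environments >= 1)
  if (cfg$h2 + cfg$env_var_share >= 1 + 1e-12) {
    stop("h2 + env_var_share must not exceed 1", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate one meiotic gamete under the Haldane model
#'
#' Crossover counts per chromosome are Poisson with mean `map length / 100`
#' (map length in cM), crossover positions uniform on the chromosome, no
#' interference; the gamete alternates between the two parental haplotypes
#' at crossovers, starting from a random one. The implied recombination
#' fraction between markers `d` Morgans apart is Haldane's
#' `r = (1 - exp(-2d)) / 2`.
#'
#' @param haplotypes 2 x m matrix of parental haplotypes (0/1 alleles).
#' @param map Marker map tibble (`marker`, `chrom`, `pos` in cM) aligned to
#'   the columns.
#' @return A 0/1 vector of length m.
#' @export
meiosis_gamete <- function(haplotypes, map) {
  stopifnot(nrow(haplotypes) == 2, ncol(haplotypes) == nrow(map))
  out <- numeric(nrow(map))
  for (chr in unique(map$chrom)) {
    jj <- which(map$chrom == chr)
    pos <- map$pos[jj]
    lo <- min(pos)
    len <- max(pos) - lo
    n_xo <- stats::rpois(1, len / 100)
    xo <- sort(stats::runif(n_xo, lo, lo + len))
    seg <- findInterval(pos, xo)
    use <- (sample.int(2L, 1L) - 1L + seg) %% 2L + 1L
    out[jj] <- haplotypes[cbind(use, jj)]
  }
  out
}

#' Simulate a NAM population with known truth
#'
#' Generates founder haplotypes (common parent vs family founders), F1s, and
#' RILs by single-seed descent with Haldane recombination; an additive
#' polygenic phenotype with environment effects scaled so the realised
#' heritability matches the target; and, when requested, MCAR missingness
#' and genotyping errors on the observed panel. Everything every other
#' module needs to be tested against a known standard.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `truth_bundle`: `geno` (complete, error-free truth
#'   panel), `observed` (panel after error/missingness injection; equal to
#'   `geno` when both rates are 0), `mask` (masked-cell record or `NULL`),
#'   `flips` (injected miscalls or `NULL`), `pedigree`, `families` (named
#'   family factor over RIL ids), `phenotypes` (tibble `id`, `env`, `value`),
#'   `genetic_values` (named true additive values), `qtl` (tibble of QTL
#'   markers and effects), `var_components` (true `sigma2_A`, `sigma2_E`,
#'   `sigma2_e`), `config`.
#' @export
simulate_nam <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, .simulate_nam_impl(cfg))
}

.simulate_nam_impl <- function(cfg) {
  m_chr <- cfg$markers_per_chromosome
  map <- purrr::map_dfr(seq_len(cfg$n_chromosomes), function(ch) {
    tibble::tibble(
      marker = sprintf("c%d_m%03d", ch, seq_len(m_chr)),
      chrom = as.character(ch),
      pos = if (m_chr == 1) 0 else
        seq(0, cfg$map_length_cM, length.out = m_chr))
  })
  m <- nrow(map)
  common <- stats::rbinom(m, 1, 0.5)
  founders <- matrix(vapply(seq_len(cfg$n_families), function(f) {
    flip <- stats::rbinom(m, 1, cfg$founder_poly_rate) == 1
    ifelse(flip, 1 - common, common)
  }, numeric(m)), nrow = m)
  fam_names <- sprintf("F%02d", seq_len(cfg$n_families))
  ril_ids <- as.vector(t(outer(fam_names, sprintf("R%03d",
                                                  seq_len(cfg$ril_per_family)),
                               paste, sep = ".")))
  families <- stats::setNames(rep(fam_names, each = cfg$ril_per_family),
                              ril_ids)
  calls <- matrix(NA_real_, length(ril_ids), m,
                  dimnames = list(ril_ids, map$marker))
  for (f in seq_len(cfg$n_families)) {
    for (r in seq_len(cfg$ril_per_family)) {
      h1 <- common
      h2 <- founders[, f]
      if (cfg$selfing_generations > 0) {
        for (g in seq_len(cfg$selfing_generations)) {
          hp <- rbind(h1, h2)
          g1 <- meiosis_gamete(hp, map)
          g2 <- meiosis_gamete(hp, map)
          h1 <- g1
          h2 <- g2
        }
      }
      calls[(f - 1) * cfg$ril_per_family + r, ] <- h1 + h2
    }
  }
  geno <- geno_matrix(calls, map = map)
  # pedigree: founders, one F1 per cross, RILs as selfing chains off the F1
  s <- cfg$selfing_generations
  ped_records <- dplyr::bind_rows(
    tibble::tibble(id = "COMMON", parent1 = NA_character_,
                   parent2 = NA_character_, selfing_generations = 0L),
    tibble::tibble(id = paste0("P.", fam_names), parent1 = NA_character_,
                   parent2 = NA_character_, selfing_generations = 0L),
    tibble::tibble(id = paste0("F1.", fam_names), parent1 = "COMMON",
                   parent2 = paste0("P.", fam_names),
                   selfing_generations = 0L),
    if (s == 0) {
      tibble::tibble(id = ril_ids, parent1 = "COMMON",
                     parent2 = paste0("P.", families[ril_ids]),
                     selfing_generations = 0L)
    } else {
      tibble::tibble(id = ril_ids,
                     parent1 = paste0("F1.", families[ril_ids]),
                     parent2 = paste0("F1.", families[ril_ids]),
                     selfing_generations = s - 1L)
    }
  )
  pedigree <- build_pedigree(ped_records)
  # additive trait on a marker-QTL subset, noise scaled to the target h2
  qtl_idx <- sort(sample.int(m, min(cfg$n_qtl, m)))
  effects <- stats::rnorm(length(qtl_idx))
  g <- drop(calls[, qtl_idx, drop = FALSE] %*% effects)
  g <- g - mean(g)
  vA <- stats::var(g)
  if (vA < 1e-12) stop("simulated genetic variance is zero; increase n_qtl ",
                       "or founder_poly_rate", call. = FALSE)
  vY <- vA / cfg$h2
  vE <- cfg$env_var_share * vY
  vRes <- vY - vA - vE
  env_names <- sprintf("env%d", seq_len(cfg$n_environments))
  env_eff <- stats::setNames(stats::rnorm(cfg$n_environments, 0, sqrt(vE)),
                             env_names)
  phenotypes <- tidyr::expand_grid(id = ril_ids, env = env_names)
  phenotypes$value <- g[match(phenotypes$id, ril_ids)] +
    env_eff[phenotypes$env] +
    stats::rnorm(nrow(phenotypes), 0, sqrt(vRes))
  observed <- geno
  flips <- NULL
  mask <- NULL
  if (cfg$genotyping_error_rate > 0) {
    err <- inject_genotyping_errors(observed, cfg$genotyping_error_rate)
    observed <- err$geno
    flips <- err$flips
  }
  if (cfg$missing_rate > 0) {
    ms <- inject_missing(observed, cfg$missing_rate)
    observed <- ms$geno
    mask <- ms$mask
  }
  structure(list(
    geno = geno, observed = observed, mask = mask, flips = flips,
    pedigree = pedigree, families = families, phenotypes = phenotypes,
    genetic_values = stats::setNames(g, ril_ids),
    qtl = tibble::tibble(marker = map$marker[qtl_idx], effect = effects),
    var_components = c(sigma2_A = vA, sigma2_E = vE, sigma2_e = vRes),
    config = cfg
  ), class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cfg <- x$config
  cat("<truth_bundle> ", cfg$n_families, " families x ", cfg$ril_per_family,
      " RILs (F", cfg$selfing_generations + 1, "), ",
      nrow(x$geno$map), " markers on ", cfg$n_chromosomes,
      " chromosomes, target h2 = ", cfg$h2, "\n", sep = "")
  invisible(x)
}

#' Inject genotyping errors (SNP miscalls)
#'
#' Flips each non-missing call, independently with probability `rate`, to
#' one of the two other ordinal values chosen uniformly. Used to exercise
#' the gene-content-heritability quality filter, which targets markers whose
#' transmission stops following the pedigree.
#'
#' @param gm A [geno_matrix()].
#' @param rate Per-cell miscall probability in `[0, 1)`.
#' @param seed Optional seed.
#' @return A list with `geno` (corrupted panel) and `flips`, a tibble of
#'   flipped cells (`id`, `marker`, `from`, `to`).
#' @export
inject_genotyping_errors <- function(gm, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  run <- function() {
    calls <- gm$calls
    cells <- which(!is.na(calls))
    hit <- cells[stats::runif(length(cells)) < rate]
    old <- calls[hit]
    new <- vapply(old, function(v) sample(setdiff(c(0, 1, 2), v), 1L),
                  numeric(1))
    calls[hit] <- new
    idx <- arrayInd(hit, dim(calls))
    list(geno = geno_matrix(calls, map = gm$map, ids = gm$ids,
                            dosage = gm$dosage),
         flips = tibble::tibble(id = gm$ids[idx[, 1]],
                                marker = gm$map$marker[idx[, 2]],
                                from = old, to = new))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
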