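# Shared fixtures built in code: tiny pedigrees, panels and populations.

# three-generation textbook pedigree: founders A,B,C,D; E = A x B, F = C x D,
# G,H = E x F (full sibs), I = G x H (inbred)
toy_pedigree <- function() {
  pedigree(animal = c("A", "B", "C", "D", "E", "F", "G", "H", "I"),
           sire = c(NA, NA, NA, NA, "A", "C", "E", "E", "G"),
           dam = c(NA, NA, NA, NA, "B", "D", "F", "F", "H"))
}

# panel with exact Hardy-Weinberg class counts for allele frequency p
hwe_exact_panel <- function(p, n = 100) {
  q <- 1 - p
  counts <- round(n * c(q^2, 2 * p * q, p^2))
  codes <- matrix(rep(c(0L, 1L, 2L), counts), ncol = 1)
  genotype_panel(codes, data.frame(snp = "s1", chrom = "1", pos = 1000L))
}

# small simulated population used by several engine tests
quick_population <- function(seed = 5, n_cows = 120, snps = 40,
                             records = c(1L, 3L), sigma_g2 = 0.3,
                             sigma_pe2 = 0.1, sigma_e2 = 0.6, ...) {
  cfg <- sim_config(seed = seed, n_founders = 40, n_generations = 2,
                    n_per_generation = 40, n_cows = n_cows, n_chrom = 2,
                    snps_per_chrom = ceiling(snps / 2),
                    chrom_length_bp = 1e7, records_range = records,
                    sigma_g2 = sigma_g2, sigma_pe2 = sigma_pe2,
                    sigma_e2 = sigma_e2,
                    fixed_effects = list(
                      hys = list(n_levels = 4, sd = 0.6),
                      parity = list(n_levels = 3, sd = 0.3),
                      age_class = list(n_levels = 3, sd = 0.2),
                      month = list(n_levels = 4, sd = 0.2)), ...)
  simulate_population(cfg)
}

# residual response for a simulated population via the pre-correction model
precorrected_response <- function(pop) {
  fit <- fit_fixed_effects(pop$pheno)
  residualize(pop$pheno, fit, animals = pop$cows)
}

# cow-cohort panel + allele stats (panel used as-is when no cohort given)
cohort_panel <- function(pop) {
  panel <- if (is.null(pop$cows)) pop$panel else
    genotype_panel(pop$panel$codes[pop$cows, , drop = FALSE], pop$panel$map)
  list(panel = panel, stats = allele_stats(panel))
}

# explicit dense GLS oracle: never uses the package's Woodbury path
gls_oracle <- function(y, animal, A, vc, covariates) {
  ids <- unique(animal)
  Z <- outer(animal, ids, "==") * 1
  As <- A[ids, ids]
  V <- Z %*% As %*% t(Z) * vc$sigma_g2 + Z %*% t(Z) * vc$sigma_pe2 +
    diag(length(y)) * vc$sigma_e2
  X <- cbind(1, covariates)
  Vi <- solve(V)
  C <- solve(t(X) %*% Vi %*% X)
  b <- drop(C %*% t(X) %*% Vi %*% y)
  se <- sqrt(diag(C))
  df2 <- length(y) - ncol(X)
  p <- stats::pf((b / se)^2, 1, df2, lower.tail = FALSE)
  list(estimate = b[-1], se = se[-1], p = p[-1])
}
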