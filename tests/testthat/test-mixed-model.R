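test_that("solver matches the explicit V-inversion GLS oracle for all variants", {
  pop <- quick_population(seed = 31, n_cows = 40, snps = 12,
                          records = c(1L, 3L))
  resp <- precorrected_response(pop)
  y <- resp$residual; animal <- resp$animal
  cp <- cohort_panel(pop)
  row_of <- match(animal, cp$panel$animal)
  # one polymorphic SNP per chromosome so the pair is not in strong LD
  ok <- c(which(cp$panel$map$chrom == "1" & cp$stats$maf > 0.15)[1],
          which(cp$panel$map$chrom == "2" & cp$stats$maf > 0.15)[1])
  vc <- variance_components(0.25, 0.15, 0.6)
  xa1 <- code_additive(cp$panel$codes[, ok[1]], cp$stats$p[ok[1]])[row_of]
  xd1 <- code_dominance(cp$panel$codes[, ok[1]], cp$stats$p[ok[1]])[row_of]
  xa2 <- code_additive(cp$panel$codes[, ok[2]], cp$stats$p[ok[2]])[row_of]

  variants <- list(additive = cbind(x_a = xa1),
                   dominance = cbind(x_a = xa1, x_d = xd1),
                   epistasis = cbind(x_a_j = xa1, x_a_k = xa2,
                                     x_e = code_epistasis(xa1, xa2)))
  for (cov in variants) {
    fit <- solve_mme(y, animal, pop$A, vc, cov)
    oracle <- gls_oracle(y, animal, pop$A, vc, cov)
    expect_equal(fit$estimate, unname(oracle$estimate), tolerance = 1e-8)
    expect_equal(fit$se, unname(oracle$se), tolerance = 1e-8)
    expect_equal(fit$p, unname(oracle$p), tolerance = 1e-8)
  }
})

test_that("with zero random variances the engine reproduces single-SNP OLS", {
  set.seed(77)
  n <- 60
  animal <- paste0("c", 1:n)
  A <- diag(n); dimnames(A) <- list(animal, animal)
  x <- stats::rnorm(n)
  y <- 0.4 * x + stats::rnorm(n)
  vc <- variance_components(0, 0, 1)
  fit <- solve_mme(y, animal, A, vc, cbind(x = x))
  ols <- summary(stats::lm(y ~ x))$coefficients
  expect_equal(fit$estimate, ols["x", "Estimate"], tolerance = 1e-10)
  # the Wald SE uses the assumed sigma_e2 = 1, the F test the same df;
  # p-values agree once OLS uses the known-variance z form
  z2 <- (fit$estimate / fit$se)^2
  expect_equal(fit$se, sqrt(solve(crossprod(cbind(1, x)))[2, 2]),
               tolerance = 1e-10)
  expect_equal(fit$p, stats::pf(z2, 1, n - 2, lower.tail = FALSE))
})

test_that("constant or collinear focal covariates are flagged not-testable", {
  pop <- quick_population(seed = 33, n_cows = 25, snps = 10)
  resp <- precorrected_response(pop)
  vc <- variance_components(0.2, 0.1, 0.7)
  fit <- solve_mme(resp$residual, resp$animal, pop$A, vc,
                   cbind(x_a = rep(1.6, nrow(resp))))
  expect_false(fit$testable)
  x <- stats::rnorm(nrow(resp))
  fit2 <- solve_mme(resp$residual, resp$animal, pop$A, vc,
                    cbind(a = x, b = 2 * x), focal = "b")
  expect_false(fit2$testable)
})

test_that("shifting the response changes only the mean, not SNP tests", {
  pop <- quick_population(seed = 34, n_cows = 40, snps = 10)
  resp <- precorrected_response(pop)
  cp <- cohort_panel(pop)
  row_of <- match(resp$animal, cp$panel$animal)
  j <- which(cp$stats$maf > 0.2)[1]
  xa <- code_additive(cp$panel$codes[, j], cp$stats$p[j])[row_of]
  vc <- variance_components(0.3, 0.1, 0.6)
  f1 <- solve_mme(resp$residual, resp$animal, pop$A, vc, cbind(x_a = xa))
  f2 <- solve_mme(resp$residual + 100, resp$animal, pop$A, vc,
                  cbind(x_a = xa))
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-9)
  expect_equal(f1$p, f2$p, tolerance = 1e-9)
})

test_that("allele relabelling flips the additive sign and preserves dominance", {
  pop <- quick_population(seed = 35, n_cows = 40, snps = 10)
  resp <- precorrected_response(pop)
  cp <- cohort_panel(pop)
  row_of <- match(resp$animal, cp$panel$animal)
  j <- which(cp$stats$maf > 0.2)[1]
  g <- cp$panel$codes[, j]; p <- cp$stats$p[j]
  vc <- variance_components(0.3, 0.1, 0.6)
  covA <- cbind(x_a = code_additive(g, p)[row_of],
                x_d = code_dominance(g, p)[row_of])
  covB <- cbind(x_a = code_additive(2L - g, 1 - p)[row_of],
                x_d = code_dominance(2L - g, 1 - p)[row_of])
  fA <- solve_mme(resp$residual, resp$animal, pop$A, vc, covA)
  fB <- solve_mme(resp$residual, resp$animal, pop$A, vc, covB)
  expect_equal(fB$estimate[1], -fA$estimate[1], tolerance = 1e-9)
  expect_equal(fB$se, fA$se, tolerance = 1e-9)
  expect_equal(fB$p, fA$p, tolerance = 1e-9)
  expect_equal(fB$estimate[2], fA$estimate[2], tolerance = 1e-9)
  # sigma_a2 = 2pq a^2 invariant under relabelling
  va <- variance_fraction(fA$estimate[1], p, vc, "additive")
  vb <- variance_fraction(fB$estimate[1], 1 - p, vc, "additive")
  expect_equal(va$sigma2_snp, vb$sigma2_snp, tolerance = 1e-12)
})

test_that("REML handles degenerate inputs gracefully", {
  pop <- quick_population(seed = 36, n_cows = 30, snps = 8,
                          records = c(1L, 1L))
  resp <- precorrected_response(pop)
  # zero-variance response
  vc0 <- reml_null(rep(3, nrow(resp)), resp$animal, pop$A)
  expect_equal(c(vc0$sigma_g2, vc0$sigma_pe2, vc0$sigma_e2), c(0, 0, 0))
  # single records: sigma_pe2 not identifiable, fixed at zero with warning
  expect_warning(vc1 <- reml_null(resp$residual, resp$animal, pop$A),
                 "repeated records")
  expect_equal(vc1$sigma_pe2, 0)
  expect_true(vc1$converged)
})

test_that("REML converges on repeated-record data with sane components", {
  pop <- quick_population(seed = 37, n_cows = 150, snps = 10,
                          records = c(2L, 3L))
  resp <- precorrected_response(pop)
  vc <- reml_null(resp$residual, resp$animal, pop$A)
  expect_true(vc$converged)
  expect_true(all(c(vc$sigma_g2, vc$sigma_pe2, vc$sigma_e2) >= 0))
  expect_gt(phenotypic_variance(vc), 0.3)
  expect_lt(phenotypic_variance(vc), 3)
  expect_true(is.finite(vc$loglik))
})

test_that("fixed-vc and per-SNP REML give closely matching p-values", {
  pop <- quick_population(seed = 38, n_cows = 200, snps = 30,
                          records = c(1L, 3L))
  resp <- precorrected_response(pop)
  cp <- cohort_panel(pop)
  row_of <- match(resp$animal, cp$panel$animal)
  vc <- reml_null(resp$residual, resp$animal, pop$A)
  ctx_snps <- which(cp$stats$maf > 0.05)[1:12]
  for (j in ctx_snps) {
    xa <- code_additive(cp$panel$codes[, j], cp$stats$p[j])[row_of]
    f1 <- fit_snp(resp$residual, resp$animal, pop$A, vc, cbind(x_a = xa),
                  mode = "fixed-vc")
    f2 <- fit_snp(resp$residual, resp$animal, pop$A, vc, cbind(x_a = xa),
                  mode = "per-snp-reml")
    expect_lt(abs(-log10(f1$p) + log10(f2$p)), 0.15)
  }
})
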