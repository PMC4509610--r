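test_that("CSV and PLINK .raw ingestion agree and validate input", {
  codes <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L), nrow = 2, byrow = TRUE,
                  dimnames = list(c("c1", "c2"), NULL))
  map <- data.frame(snp = c("s1", "s2", "s3"), chrom = "1",
                    pos = c(500L, 100L, 900L))
  mt <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,s1,s2,s3", "c1,0,1,2", "c2,2,1,0"), mt)
  writeLines(c("snp,chrom,pos", "s1,1,500", "s2,1,100", "s3,1,900"), mp)
  pan <- read_genotypes(mt, mp, dialect = "csv")
  expect_equal(dim(pan$codes), c(2L, 3L))
  # internal sort by position: s2 first
  expect_identical(pan$map$snp, c("s2", "s1", "s3"))
  expect_identical(unname(pan$codes["c1", ]), c(1L, 0L, 2L))

  raw <- withr::local_tempfile(fileext = ".raw")
  rmap <- withr::local_tempfile(fileext = ".map")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE s1_A s2_G s3_T",
               "f1 c1 0 0 2 -9 0 1 2", "f2 c2 0 0 2 -9 2 1 0"), raw)
  writeLines(c("1 s1 0 500", "1 s2 0 100", "1 s3 0 900"), rmap)
  pan2 <- read_genotypes(raw, rmap, dialect = "plink-raw")
  expect_equal(pan2$codes, pan$codes)
  expect_equal(pan2$map, pan$map)

  expect_error(genotype_panel(codes, map[1:2, ]), "map rows")
  expect_error(genotype_panel(matrix(3L, 1, 1),
                              data.frame(snp = "x", chrom = "1", pos = 1L)),
               "codes must be")
  expect_error(genotype_panel(matrix(0L, 1, 2),
                              data.frame(snp = c("d", "d"), chrom = "1",
                                         pos = c(1L, 2L))),
               "duplicate.*d")
})

test_that("allele and genotype-class statistics follow counting definitions", {
  codes <- cbind(a = c(0L, 1L, 2L), b = c(2L, 2L, 2L), c = c(0L, NA, 2L))
  pan <- genotype_panel(codes, data.frame(snp = c("a", "b", "c"),
                                          chrom = "1", pos = 1:3))
  st <- allele_stats(pan)
  expect_equal(st$p[st$snp == "a"], 0.5)
  expect_equal(unlist(st[st$snp == "a", c("f_aa", "f_Aa", "f_AA")]),
               c(f_aa = 1, f_Aa = 1, f_AA = 1) / 3)
  expect_equal(st$p[st$snp == "b"], 1)
  expect_equal(st$min_class_freq[st$snp == "b"], 0)
  expect_equal(st$p[st$snp == "c"], 0.5)   # over called animals only
  # 4-animal arithmetic case
  pan4 <- genotype_panel(matrix(c(0L, 0L, 1L, 2L), ncol = 1),
                         data.frame(snp = "s", chrom = "1", pos = 1L))
  expect_equal(allele_stats(pan4)$p, 3 / 8)
})

test_that("genotype-class filter removes SNPs rare in any population and is idempotent", {
  # SNP f1 fails in pop2 only; f2 passes everywhere; f3 fails in pop1
  codes1 <- cbind(f1 = rep(c(0L, 1L, 2L), c(25, 50, 25)),
                  f2 = rep(c(0L, 1L, 2L), c(25, 50, 25)),
                  f3 = rep(c(0L, 1L, 2L), c(0, 50, 50)))
  codes2 <- cbind(f1 = rep(c(0L, 1L, 2L), c(0, 30, 170)),
                  f2 = rep(c(0L, 1L, 2L), c(50, 100, 50)),
                  f3 = rep(c(0L, 1L, 2L), c(50, 100, 50)))
  map <- data.frame(snp = c("f1", "f2", "f3"), chrom = "1", pos = 1:3)
  p1 <- genotype_panel(codes1, map); p2 <- genotype_panel(codes2, map)
  res <- filter_by_genotype_class(p1, list(pop1 = allele_stats(p1),
                                           pop2 = allele_stats(p2)),
                                  min_class_freq = 0.01)
  expect_identical(res$panel$map$snp, "f2")
  expect_equal(res$n_retained, 1L)
  expect_equal(res$n_removed, 2L)
  # threshold examples: class freq 0.009 removed, balanced SNP retained
  cds <- cbind(r = rep(c(0L, 1L, 2L), c(9, 300, 691)),
               k = rep(c(0L, 1L, 2L), c(250, 500, 250)))
  pp <- genotype_panel(cds, data.frame(snp = c("r", "k"), chrom = "1",
                                       pos = 1:2))
  out <- filter_by_genotype_class(pp, allele_stats(pp), 0.01)
  expect_identical(out$panel$map$snp, "k")
  # idempotent
  st2 <- allele_stats(out$panel)
  again <- filter_by_genotype_class(out$panel, st2, 0.01)
  expect_identical(again$panel$map$snp, out$panel$map$snp)
  expect_equal(again$n_removed, 0L)
})

test_that("additive and dominance codings match their defining maps", {
  expect_equal(code_additive(c(0L, 1L, 2L), 0.5), c(-1, 0, 1))
  expect_equal(code_additive(c(0L, 1L, 2L), 0.2), c(-0.4, 0.6, 1.6))
  expect_equal(code_dominance(c(0L, 1L, 2L), 0.5), c(-0.5, 0.5, -0.5))
  expect_equal(code_dominance(c(0L, 1L, 2L), 0.2), c(-0.08, 0.32, -1.28))
  expect_error(code_additive(c(0L, 1L), 1), "degenerate")
  expect_error(code_dominance(c(0L, 1L), 0), "degenerate")
  # constant covariate when all animals share a genotype
  expect_equal(code_additive(rep(2L, 5), 0.2), rep(1.6, 5))
  # missing codes imputed to the mean of observed coded values
  x <- code_additive(c(0L, 2L, NA), 0.5)
  expect_equal(x[3], mean(x[1:2]))
})

test_that("codings are exactly centered and orthogonal under exact HWE", {
  for (p in c(0.2, 0.5, 0.7)) {
    pan <- hwe_exact_panel(p, n = 400)
    st <- allele_stats(pan)
    xa <- code_additive(pan$codes[, 1], st$p)
    xd <- code_dominance(pan$codes[, 1], st$p)
    # coded with the *class-count* frequency the panel was built from
    expect_equal(mean(code_additive(pan$codes[, 1], p)), 0, tolerance = 1e-12)
    expect_equal(mean(code_dominance(pan$codes[, 1], p)), 0, tolerance = 1e-12)
    expect_equal(sum(code_additive(pan$codes[, 1], p) *
                       code_dominance(pan$codes[, 1], p)), 0,
                 tolerance = 1e-9)
  }
})

test_that("sampled HWE panels have mean ~0 and Var(x_a) ~ 2pq, Var(x_d) ~ (2pq)^2", {
  set.seed(404)
  n <- 5000
  for (p in c(0.3, 0.5)) {
    g <- stats::rbinom(n, 2, p)
    xa <- code_additive(g, p)
    xd <- code_dominance(g, p)
    se_a <- sqrt(2 * p * (1 - p) / n)
    expect_lt(abs(mean(xa)), 3 * se_a)
    expect_lt(abs(stats::var(xa) - 2 * p * (1 - p)), 0.05)
    expect_lt(abs(stats::var(xd) - (2 * p * (1 - p))^2), 0.05)
    expect_lt(abs(stats::cor(xa, xd)), 3 / sqrt(n) * 1.5 + 0.05)
  }
})

test_that("interaction covariate is the elementwise product with known hazards", {
  expect_equal(code_epistasis(c(-1, 0, 1), c(-1, 0, 1)), c(1, 0, 1))
  expect_equal(code_epistasis(c(-1, 0, 1), rep(0, 3)), rep(0, 3))
  # complete LD: product equals x_a^2, i.e. a dominance-like contrast
  xa <- code_additive(c(0L, 1L, 2L, 1L), 0.5)
  expect_equal(code_epistasis(xa, xa), xa^2)
  expect_error(code_epistasis(1:3, 1:2), "equal length")
})
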