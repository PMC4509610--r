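test_that("identical configurations give byte-identical populations", {
  cfg <- sim_config(seed = 61, n_founders = 20, n_generations = 2,
                    n_per_generation = 20, n_cows = 20, n_chrom = 2,
                    snps_per_chrom = 15, chrom_length_bp = 1e7)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$ped$animal, p2$ped$animal)
  expect_identical(p1$panel$codes, p2$panel$codes)
  expect_identical(p1$pheno, p2$pheno)
  cfg2 <- cfg; cfg2$seed <- 62
  p3 <- simulate_population(cfg2)
  expect_false(identical(p1$pheno$value, p3$pheno$value))
})

test_that("simulated pedigrees have known parents, depth, and an all-female cohort", {
  cfg <- sim_config(seed = 63, n_founders = 10, n_generations = 3,
                    n_per_generation = 12, n_cows = 8)
  ped <- simulate_pedigree(cfg)
  expect_equal(max(ped$generation), 3L)
  expect_equal(ped$n_generations, 3L)
  last <- ped$animal[ped$generation == 3L]
  expect_length(last, 8)
  expect_true(all(ped$sex[last] == "F"))
  nonf <- ped$animal[ped$generation > 0L]
  idx <- match(nonf, ped$animal)
  expect_false(any(is.na(ped$sire[idx])) || any(is.na(ped$dam[idx])))
  expect_length(ped$animal, 10 + 12 + 12 + 8)
})

test_that("gene dropping is Mendelian-consistent on a small simulation", {
  cfg <- sim_config(seed = 64, n_founders = 12, n_generations = 2,
                    n_per_generation = 12, n_cows = 12, n_chrom = 1,
                    snps_per_chrom = 20, chrom_length_bp = 1e7)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  g <- geno$panel$codes
  for (i in which(ped$sire_idx > 0)) {
    gs <- g[ped$sire_idx[i], ]; gd <- g[ped$dam_idx[i], ]; gc <- g[i, ]
    # child inherits exactly one allele from each parent
    cmin <- (gs == 2L) + (gd == 2L)
    cmax <- (gs >= 1L) + (gd >= 1L)
    expect_true(all(gc >= cmin & gc <= cmax))
  }
})

test_that("LD decays with map distance and duplicated columns have r2 = 1", {
  cfg <- sim_config(seed = 65, n_founders = 150, n_generations = 1,
                    n_per_generation = 150, n_cows = 250, n_chrom = 1,
                    snps_per_chrom = 80, chrom_length_bp = 2e7,
                    n_hap_pool = 6, mosaic_block_bp = 1e6)
  pop <- simulate_population(cfg)
  g <- pop$panel$codes[pop$cows, ]
  pos <- pop$panel$map$pos
  keep <- which(apply(g, 2, stats::sd) > 0)
  pairs <- t(utils::combn(keep, 2))
  set.seed(650)
  pairs <- pairs[sample.int(nrow(pairs), 800), ]
  d <- abs(pos[pairs[, 1]] - pos[pairs[, 2]])
  r2 <- vapply(seq_len(nrow(pairs)), function(k)
    stats::cor(g[, pairs[k, 1]], g[, pairs[k, 2]])^2, numeric(1))
  # mean r2 over distance bins decreases in rank
  bins <- cut(d, c(0, 5e5, 1e6, 2e6, 5e6, 1e7, 2e7))
  mb <- tapply(r2, bins, mean)
  expect_lt(stats::cor(seq_along(mb), mb, method = "spearman"), -0.5)
  # near pairs carry real LD, far pairs little
  expect_gt(mean(r2[d < 5e5]), mean(r2[d > 5e6]) + 0.05)
  expect_equal(stats::cor(g[, keep[1]], g[, keep[1]])^2, 1)
})

test_that("founder genotypes are approximately in Hardy-Weinberg proportions", {
  cfg <- sim_config(seed = 66, n_founders = 400, n_generations = 1,
                    n_per_generation = 10, n_cows = 10, n_chrom = 2,
                    snps_per_chrom = 50, chrom_length_bp = 2e7,
                    n_hap_pool = 40)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  founders <- ped$animal[ped$generation == 0L]
  g <- geno$panel$codes[founders, ]
  pvals <- apply(g, 2, function(col) {
    p <- mean(col) / 2
    if (p <= 0.02 || p >= 0.98) return(NA_real_)
    expc <- length(col) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- c(sum(col == 0), sum(col == 1), sum(col == 2))
    stats::pchisq(sum((obs - expc)^2 / expc), df = 1, lower.tail = FALSE)
  })
  pvals <- pvals[!is.na(pvals)]
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("hidden causal tags hit their r2 targets within tolerance", {
  cfg <- sim_config(seed = 67, n_founders = 200, n_generations = 2,
                    n_per_generation = 200, n_cows = 300, n_chrom = 1,
                    snps_per_chrom = 20, chrom_length_bp = 2e7,
                    hidden_causal = list(chrom = 1, maf = 0.3, var_frac = 0.02,
                                         n_tags = 6,
                                         r2_targets = seq(0.3, 0.9,
                                                          length.out = 6)))
  pop <- simulate_population(cfg)
  tr <- pop$truth$hidden$tag_r2
  expect_equal(nrow(tr), 6)
  expect_true(all(abs(tr$r2_founder - tr$r2_target) <= 0.1))
  expect_false("hidden_causal" %in% pop$panel$map$snp)
  expect_length(pop$truth$hidden$genotype, length(pop$cows))
  # split tags sit between causal and a one-sided mask: D' = 1 structure
  cfg$hidden_causal$tag_mode <- "split"
  cfg$hidden_causal$proxy_r2 <- 1
  pop2 <- simulate_population(cfg)
  tr2 <- pop2$truth$hidden$tag_r2
  expect_true("tag_proxy" %in% tr2$snp)
  expect_equal(tr2$r2_founder[tr2$snp == "tag_proxy"], 1)
  expect_gt(min(tr2$r2_genotype[tr2$snp == "tag_proxy"]), 0.97)
})

test_that("cow-mean variance matches sigma_g2 + sigma_e2 / k in closed form", {
  reps <- 40
  vars <- numeric(reps)
  k <- 2
  for (r in seq_len(reps)) {
    cfg <- sim_config(seed = 700 + r, n_founders = 300, n_generations = 1,
                      n_per_generation = 10, n_cows = 300, n_chrom = 1,
                      snps_per_chrom = 5, chrom_length_bp = 1e7,
                      records_range = c(k, k), sigma_g2 = 0.4,
                      sigma_pe2 = 0, sigma_e2 = 0.6,
                      fixed_effects = list(
                        hys = list(n_levels = 2, sd = 0),
                        parity = list(n_levels = 2, sd = 0),
                        age_class = list(n_levels = 2, sd = 0),
                        month = list(n_levels = 2, sd = 0)))
    pop <- simulate_population(cfg)
    cow_means <- tapply(pop$pheno$value, pop$pheno$animal, mean)
    vars[r] <- stats::var(cow_means)
  }
  target <- 0.4 + 0.6 / k
  expect_lt(abs(mean(vars) - target), 3 * stats::sd(vars) / sqrt(reps))
})

test_that("two-breed simulations share the map and part of the haplotype pool", {
  base <- list(n_founders = 60, n_generations = 2, n_per_generation = 60,
               n_cows = 60, n_chrom = 1, snps_per_chrom = 30,
               chrom_length_bp = 1e7)
  cfg_a <- do.call(sim_config, c(list(seed = 81), base))
  cfg_b <- do.call(sim_config, c(list(seed = 82), base))
  two <- simulate_two_breeds(cfg_a, cfg_b, pool_overlap = 0.5)
  expect_identical(two$a$panel$map, two$b$panel$map)
  shared <- seq_len(15)
  expect_identical(two$a$pool[[1]][shared, ], two$b$pool[[1]][shared, ])
  expect_false(identical(two$a$pool[[1]], two$b$pool[[1]]))
  expect_false(identical(two$a$panel$codes, two$b$panel$codes))
})

test_that("simulation files round-trip through the pipeline readers", {
  pop <- quick_population(seed = 85, n_cows = 20, snps = 10)
  dir <- withr::local_tempdir()
  write_sim_files(pop, dir)
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_setequal(ped$animal, pop$ped$animal)
  pan <- read_genotypes(file.path(dir, "genotypes.csv"),
                        file.path(dir, "map.csv"), dialect = "csv")
  expect_equal(pan$codes[pop$panel$animal, ], pop$panel$codes)
  ph <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  expect_equal(nrow(ph), nrow(pop$pheno))
  expect_equal(ph$value, pop$pheno$value)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$sigma_g2, pop$truth$sigma_g2)
})
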