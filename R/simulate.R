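# Synthetic populations with known genetic architecture: multi-generation
# pedigrees, LD-structured genotypes (founder haplotypes are mosaics of a
# small base pool, then gene-dropped with recombination), optionally a
# hidden causal variant tagged imperfectly by nearby panel SNPs, and
# repeated-record phenotypes with herd-year-season / parity / age / month
# fixed effects. Every run emits a truth ledger for parameter-recovery
# tests.

derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 9973) %% 2147483629)
}

#' Simulation configuration
#'
#' Defaults are a desk-scale preset: a four-generation pedigree ending in a
#' cohort of 2,000 cows, 5,000 SNPs on 5 chromosomes, a moderately
#' heritable trait (`sigma_g2/sigma_p2 = 0.3`) with permanent-environment
#' variance and 1-5 records per cow. Lower `sigma_g2` (e.g. 0.04) emulates
#' a low-heritability fertility-like trait.
#'
#' @param seed integer seed; fixes every stage of the simulation.
#' @param map_seed seed for the marker map layout only (defaults to
#'   `seed`); two populations sharing `map_seed` and genome parameters get
#'   identical maps, as needed for cross-population validation.
#' @param n_founders founder animals (half male, half female).
#' @param n_generations generations after the founders; the final
#'   generation is all-female (the recorded cow cohort).
#' @param n_per_generation animals born in each intermediate generation.
#' @param n_cows animals in the final generation.
#' @param n_chrom,snps_per_chrom,chrom_length_bp genome layout.
#' @param n_hap_pool base haplotypes in the founder pool.
#' @param mosaic_block_bp mean template-switch distance when founder
#'   haplotypes are copied as mosaics of the pool (sets the LD range).
#' @param recomb_rate_per_bp per-bp recombination rate during gene dropping
#'   (default 1e-8, i.e. 1 cM/Mb).
#' @param freq_range range of base-pool allele frequencies.
#' @param causal data.frame (`snp`, `a`, `d`): per-locus additive and
#'   dominance effects on the corrected-covariate scale; `snp` may be a
#'   panel SNP id or an index in map order.
#' @param causal_pairs data.frame (`snp_j`, `snp_k`, `aa`) of pairwise
#'   additive x additive effects.
#' @param sigma_g2,sigma_pe2,sigma_e2 polygenic, permanent-environment and
#'   residual variances (trait units squared).
#' @param mu population mean.
#' @param records_range integer range of records per cow.
#' @param fixed_effects named list of `list(n_levels, sd)` for `hys`,
#'   `parity`, `age_class`, `month`.
#' @param hidden_causal `NULL`, or a list describing an untyped causal
#'   variant with imperfect panel tags: `chrom`, `maf`, `a` (or `var_frac`,
#'   its additive variance as a fraction of `sigma_p2`), `d`, `n_tags`,
#'   `r2_targets` (recycled over tags), `max_tag_bp` (maximum tag distance,
#'   default 5e5), `r2_tol` (acceptance half-width, default 0.1),
#'   `tag_mode` (`"flip"`: independent allele flips; `"split"`: each tag
#'   allele covers every causal haplotype plus an independent mask, so tag
#'   *pairs* jointly recover the causal allele — the haplotype-combination
#'   structure behind LD-induced interaction artifacts), and optionally
#'   `proxy_r2`/`proxy_bp` to add one near-perfect proxy SNP (`tag_proxy`)
#'   emulating a panel variant in near-complete LD with the causal mutation.
#' @param pool optional pre-built base haplotype pool (list of per-chrom 0/1
#'   matrices) for sharing between populations.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1, map_seed = seed,
                       n_founders = 200, n_generations = 4,
                       n_per_generation = n_founders, n_cows = 2000,
                       n_chrom = 5, snps_per_chrom = 1000,
                       chrom_length_bp = 5e7,
                       n_hap_pool = 30, mosaic_block_bp = 1e6,
                       recomb_rate_per_bp = 1e-8,
                       freq_range = c(0.1, 0.9),
                       causal = NULL, causal_pairs = NULL,
                       sigma_g2 = 0.3, sigma_pe2 = 0.1, sigma_e2 = 0.6,
                       mu = 0, records_range = c(1L, 5L),
                       fixed_effects = list(
                         hys = list(n_levels = 15, sd = 1),
                         parity = list(n_levels = 4, sd = 0.5),
                         age_class = list(n_levels = 5, sd = 0.3),
                         month = list(n_levels = 12, sd = 0.3)),
                       hidden_causal = NULL,
                       pool = NULL) {
  stopifnot(n_founders >= 2, n_generations >= 1,
            sigma_g2 >= 0, sigma_pe2 >= 0, sigma_e2 >= 0,
            records_range[1] >= 1, records_range[2] >= records_range[1])
  structure(as.list(environment()), class = "sim_config")
}

#' Read a simulation configuration from a JSON file
#'
#' Keys are [sim_config()] argument names; `causal` and `causal_pairs` are
#' arrays of objects.
#'
#' @param path JSON file.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, args)
}

#' Simulate a discrete-generation pedigree
#'
#' Founders are unrelated; each later animal draws a sire from the males
#' and a dam from the females of the previous generation (random
#' non-self matings). The final generation is all-female.
#'
#' @param config a [sim_config()].
#' @return a [pedigree()] with extra elements `sex` and `generation`
#'   (named by animal).
#' @export
simulate_pedigree <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  id <- paste0("F", seq_len(config$n_founders))
  sex <- sample(rep(c("M", "F"), length.out = config$n_founders))
  sire <- rep(NA_character_, config$n_founders)
  dam <- rep(NA_character_, config$n_founders)
  gen <- rep(0L, config$n_founders)
  prev <- id; prev_sex <- sex
  for (g in seq_len(config$n_generations)) {
    last <- g == config$n_generations
    n_g <- if (last) config$n_cows else config$n_per_generation
    males <- prev[prev_sex == "M"]; females <- prev[prev_sex == "F"]
    if (!length(males) || !length(females))
      stop("generation ", g - 1L, " lacks one sex; cannot mate")
    s <- sample(males, n_g, replace = TRUE)
    d <- sample(females, n_g, replace = TRUE)
    a <- paste0("G", g, "_", seq_len(n_g))
    x <- if (last) rep("F", n_g) else
      sample(rep(c("M", "F"), length.out = n_g))
    id <- c(id, a); sire <- c(sire, s); dam <- c(dam, d)
    sex <- c(sex, x); gen <- c(gen, rep(g, n_g))
    prev <- a; prev_sex <- x
  }
  ped <- pedigree(id, sire, dam)
  ped$sex <- stats::setNames(sex, id)[ped$animal]
  ped$generation <- stats::setNames(gen, id)[ped$animal]
  ped
}

# mosaic copy of base pool haplotypes: template switches are Poisson along
# the chromosome with mean spacing mosaic_block_bp
mosaic_haplotype <- function(pool, pos, length_bp, block_bp) {
  K <- nrow(pool)
  n_switch <- stats::rpois(1, length_bp / block_bp)
  brk <- sort(stats::runif(n_switch, 0, length_bp))
  seg <- findInterval(pos, brk) + 1L
  templ <- sample.int(K, length(brk) + 1L, replace = TRUE)
  pool[cbind(templ[seg], seq_along(pos))]
}

# recombined gamete from one parent's two haplotypes on one chromosome
recombine <- function(h1, h2, pos, length_bp, rate) {
  n_x <- stats::rpois(1, rate * length_bp)
  brk <- sort(stats::runif(n_x, 0, length_bp))
  seg <- findInterval(pos, brk)
  phase <- (seg + stats::rbinom(1, 1, 0.5)) %% 2L
  ifelse(phase == 0L, h1, h2)
}

# flip a fraction of haplotype alleles until the squared correlation with
# the causal column hits the target within tol; r2_target = 1 copies the
# causal column exactly (a perfect proxy)
make_tag_column <- function(causal_hap, r2_target, tol, max_retries) {
  if (r2_target >= 1)
    return(list(tag = causal_hap, r2 = 1))
  eps0 <- (1 - sqrt(r2_target)) / 2
  best <- NULL; best_gap <- Inf
  for (try in seq_len(max_retries)) {
    eps <- min(max(eps0 * stats::runif(1, 0.5, 1.5), 0.001), 0.49)
    flip <- stats::rbinom(length(causal_hap), 1, eps)
    tag <- ifelse(flip == 1L, 1L - causal_hap, causal_hap)
    r2 <- suppressWarnings(stats::cor(causal_hap, tag)^2)
    if (!is.finite(r2)) next
    gap <- abs(r2 - r2_target)
    if (gap < best_gap) { best <- tag; best_gap <- gap; best_r2 <- r2 }
    if (gap <= tol / 2) break
  }
  if (best_gap > tol)
    stop(sprintf("could not reach tag r2 target %.2f (best achieved %.2f)",
                 r2_target, best_r2))
  list(tag = best, r2 = best_r2)
}

# one-sided tag for a young mutation: the tag allele is carried by every
# causal haplotype plus an independent set of non-causal haplotypes (D' = 1),
# with the mask frequency chosen so cor(tag, causal)^2 hits r2_target:
#   r2 = pc (1 - pt) / ((1 - pc) pt)  =>  pt = pc / (r2 (1 - pc) + pc).
# Any two such tags jointly recover the causal allele as the AND of their
# haplotypes, so allele *combinations* are in much higher LD with the causal
# variant than any single tag.
make_split_tag_column <- function(causal_hap, r2_target) {
  pc <- mean(causal_hap)
  pt <- pc / (r2_target * (1 - pc) + pc)
  fm <- min(max((pt - pc) / (1 - pc), 0), 1)
  tag <- causal_hap
  z <- causal_hap == 0L
  tag[z] <- stats::rbinom(sum(z), 1, fm)
  list(tag = tag, r2 = suppressWarnings(stats::cor(causal_hap, tag)^2))
}

# marker map layout, drawn under map_seed so populations can share it
sim_map <- function(config) {
  set.seed(derive_seed(config$map_seed, 2L))
  L <- config$chrom_length_bp
  hc <- config$hidden_causal
  maps <- vector("list", config$n_chrom)
  for (ch in seq_len(config$n_chrom)) {
    pos <- sort(sample.int(L - 1L, config$snps_per_chrom))
    maps[[ch]] <- data.frame(snp = sprintf("snp%d_%04d", ch,
                                           seq_along(pos)),
                             chrom = as.character(ch), pos = pos,
                             hidden = FALSE, tag_r2_target = NA_real_,
                             stringsAsFactors = FALSE)
  }
  if (!is.null(hc)) {
    ch <- if (is.null(hc$chrom)) 1L else as.integer(hc$chrom)
    max_tag_bp <- if (is.null(hc$max_tag_bp)) 5e5 else hc$max_tag_bp
    pos_c <- as.integer(L / 2)
    r2t <- rep(hc$r2_targets, length.out = hc$n_tags)
    tag_pos <- pos_c + sample(c(-1L, 1L), hc$n_tags, replace = TRUE) *
      sample.int(max_tag_bp, hc$n_tags)
    tag_pos <- pmin(pmax(tag_pos, 1L), L - 1L)
    extra <- data.frame(snp = c("hidden_causal",
                                sprintf("tag_%02d", seq_len(hc$n_tags))),
                        chrom = as.character(ch),
                        pos = c(pos_c, tag_pos),
                        hidden = c(TRUE, rep(FALSE, hc$n_tags)),
                        tag_r2_target = c(NA_real_, r2t),
                        stringsAsFactors = FALSE)
    if (!is.null(hc$proxy_r2)) {
      proxy_bp <- if (is.null(hc$proxy_bp)) 2e4 else hc$proxy_bp
      extra <- rbind(extra,
                     data.frame(snp = "tag_proxy", chrom = as.character(ch),
                                pos = pos_c + as.integer(proxy_bp),
                                hidden = FALSE, tag_r2_target = hc$proxy_r2,
                                stringsAsFactors = FALSE))
    }
    maps[[ch]] <- rbind(maps[[ch]], extra)
  }
  map <- do.call(rbind, maps)
  map <- map[order(map$chrom, map$pos, map$snp), ]
  rownames(map) <- NULL
  map
}

# base haplotype pool per chromosome; the hidden causal column is kept
# polymorphic
make_pool <- function(map, config) {
  hc <- config$hidden_causal
  lapply(seq_len(config$n_chrom), function(ch) {
    mp <- map[map$chrom == as.character(ch), ]
    f <- stats::runif(nrow(mp), config$freq_range[1], config$freq_range[2])
    if (!is.null(hc) && any(mp$hidden)) f[mp$hidden] <- hc$maf
    m <- matrix(stats::rbinom(config$n_hap_pool * nrow(mp), 1,
                              rep(f, each = config$n_hap_pool)),
                nrow = config$n_hap_pool)
    if (!is.null(hc) && any(mp$hidden)) {
      j <- which(mp$hidden)
      while (length(unique(m[, j])) < 2)
        m[, j] <- stats::rbinom(config$n_hap_pool, 1, hc$maf)
    }
    colnames(m) <- mp$snp
    m
  })
}

#' Simulate LD-structured genotypes through a pedigree
#'
#' Founder haplotypes are mosaics of a small base pool (creating LD that
#' decays with distance on the `mosaic_block_bp` scale) and are gene-dropped
#' through the pedigree with recombination. When `hidden_causal` is
#' configured, the causal locus is simulated alongside the panel but
#' excluded from it, and `n_tags` panel SNPs near it are constructed to hit
#' the requested r-squared targets (realized values are checked on founder
#' haplotypes and re-drawn until within tolerance).
#'
#' @param ped a [simulate_pedigree()] result (or any [pedigree()]).
#' @param config a [sim_config()].
#' @return list with `panel` (a [genotype_panel()] of all pedigree
#'   animals), `truth` (partial ledger: `hidden` with the causal genotype
#'   vector and per-tag realized r-squared, `pool_freq`) and `pool`.
#' @export
simulate_genotypes <- function(ped, config) {
  map <- sim_map(config)
  set.seed(derive_seed(config$seed, 12L))
  n_chrom <- config$n_chrom
  L <- config$chrom_length_bp
  hc <- config$hidden_causal
  pool <- config$pool
  if (is.null(pool)) pool <- make_pool(map, config)

  n <- length(ped$animal)
  founder <- ped$sire_idx == 0L & ped$dam_idx == 0L
  n_loci <- nrow(map)
  H1 <- matrix(0L, n, n_loci, dimnames = list(ped$animal, map$snp))
  H2 <- H1
  chrom_of <- map$chrom
  pos_of <- map$pos
  chrom_cols <- split(seq_len(n_loci), chrom_of)

  for (i in which(founder)) {
    for (ch in names(chrom_cols)) {
      cols <- chrom_cols[[ch]]
      pl <- pool[[as.integer(ch)]][, map$snp[cols], drop = FALSE]
      H1[i, cols] <- mosaic_haplotype(pl, pos_of[cols], L,
                                      config$mosaic_block_bp)
      H2[i, cols] <- mosaic_haplotype(pl, pos_of[cols], L,
                                      config$mosaic_block_bp)
    }
  }

  # hidden causal tags: rewrite tag columns of founder haplotypes
  tag_r2 <- NULL
  if (!is.null(hc)) {
    r2_tol <- if (is.null(hc$r2_tol)) 0.1 else hc$r2_tol
    max_retries <- if (is.null(hc$max_retries)) 100L else hc$max_retries
    tag_mode <- if (is.null(hc$tag_mode)) "flip" else hc$tag_mode
    ci <- which(map$snp == "hidden_causal")
    fi <- which(founder)
    causal_hap <- c(H1[fi, ci], H2[fi, ci])
    tags <- which(startsWith(map$snp, "tag_"))
    tag_r2 <- data.frame(snp = map$snp[tags],
                         r2_target = map$tag_r2_target[tags],
                         r2_founder = NA_real_, stringsAsFactors = FALSE)
    for (k in seq_along(tags)) {
      made <- if (map$snp[tags[k]] == "tag_proxy" || tag_mode == "flip")
        make_tag_column(causal_hap, tag_r2$r2_target[k], r2_tol, max_retries)
      else
        make_split_tag_column(causal_hap, tag_r2$r2_target[k])
      H1[fi, tags[k]] <- made$tag[seq_along(fi)]
      H2[fi, tags[k]] <- made$tag[length(fi) + seq_along(fi)]
      tag_r2$r2_founder[k] <- made$r2
    }
  }

  # gene dropping in topological order
  for (i in which(!founder)) {
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    for (ch in names(chrom_cols)) {
      cols <- chrom_cols[[ch]]
      H1[i, cols] <- recombine(H1[s, cols], H2[s, cols], pos_of[cols], L,
                               config$recomb_rate_per_bp)
      H2[i, cols] <- recombine(H1[d, cols], H2[d, cols], pos_of[cols], L,
                               config$recomb_rate_per_bp)
    }
  }

  geno <- H1 + H2
  hidden_cols <- which(map$hidden)
  truth <- list(pool_freq = lapply(pool, colMeans))
  if (length(hidden_cols)) {
    g_c <- geno[, hidden_cols[1]]
    tags <- which(startsWith(map$snp, "tag_"))
    tag_r2$r2_genotype <- vapply(tags, function(j)
      suppressWarnings(stats::cor(g_c, geno[, j])^2), numeric(1))
    truth$hidden <- list(snp = "hidden_causal",
                         chrom = map$chrom[hidden_cols[1]],
                         pos = map$pos[hidden_cols[1]],
                         genotype = g_c, tag_r2 = tag_r2)
  }
  keep <- setdiff(seq_len(n_loci), hidden_cols)
  panel <- genotype_panel(geno[, keep, drop = FALSE],
                          map[keep, c("snp", "chrom", "pos")])
  list(panel = panel, truth = truth, pool = pool)
}

#' Simulate repeated-record phenotypes
#'
#' Record value = mu + fixed-effect levels + causal-locus effects (on the
#' allele-frequency-corrected covariate scale, using frequencies realized
#' in the recorded cohort) + polygenic value (pedigree Cholesky with
#' variance `sigma_g2`) + per-cow permanent-environment effect + residual.
#' Records per cow are uniform over `records_range`.
#'
#' @param ped a [simulate_pedigree()] result.
#' @param geno a [simulate_genotypes()] result.
#' @param config a [sim_config()].
#' @param cows animal ids to record; default the final all-female
#'   generation.
#' @param A optional precomputed relationship matrix (else built here).
#' @param A_chol optional upper-triangular Cholesky factor of `A`, cached
#'   across replicate draws on a fixed pedigree.
#' @return list with `pheno` (a phenotype data.frame as read by
#'   [read_phenotypes()]), and `truth` (class `"sim_truth"`): causal table,
#'   variance components, true breeding values, fixed-effect level tables,
#'   hidden-causal ledger.
#' @export
simulate_phenotypes <- function(ped, geno, config, cows = NULL, A = NULL,
                                A_chol = NULL) {
  set.seed(derive_seed(config$seed, 3L))
  if (is.null(cows))
    cows <- ped$animal[ped$generation == max(ped$generation) &
                         ped$sex == "F"]
  panel <- geno$panel
  if (is.null(A_chol)) {
    if (is.null(A)) A <- build_A(ped)
    A_chol <- chol(A)
  }
  n_all <- length(ped$animal)

  u <- as.vector(crossprod(A_chol, stats::rnorm(n_all))) *
    sqrt(config$sigma_g2)
  names(u) <- ped$animal

  cow_rows <- match(cows, panel$animal)
  g_val <- stats::setNames(numeric(length(cows)), cows)
  causal_tab <- NULL

  xa_of_codes <- function(codes) {
    p <- mean(codes) / 2
    if (p <= 0 || p >= 1) return(NULL)
    list(xa = code_additive(codes, p), xd = code_dominance(codes, p), p = p)
  }
  resolve <- function(snp) {
    if (is.numeric(snp)) panel$map$snp[snp] else as.character(snp)
  }
  if (!is.null(config$causal) && nrow(config$causal)) {
    for (r in seq_len(nrow(config$causal))) {
      id <- resolve(config$causal$snp[r])
      j <- match(id, panel$map$snp)
      if (is.na(j)) stop("causal locus not in panel: ", id)
      cc <- xa_of_codes(panel$codes[cow_rows, j])
      if (is.null(cc)) stop("causal locus monomorphic in cows: ", id)
      a <- config$causal$a[r]
      d <- if ("d" %in% names(config$causal)) config$causal$d[r] else 0
      g_val <- g_val + cc$xa * a + cc$xd * d
      causal_tab <- rbind(causal_tab,
                          data.frame(snp = id, a = a, d = d, p = cc$p,
                                     var_a = 2 * cc$p * (1 - cc$p) * a^2,
                                     var_d = 4 * cc$p^2 * (1 - cc$p)^2 * d^2,
                                     stringsAsFactors = FALSE))
    }
  }
  pair_tab <- NULL
  if (!is.null(config$causal_pairs) && nrow(config$causal_pairs)) {
    for (r in seq_len(nrow(config$causal_pairs))) {
      idj <- resolve(config$causal_pairs$snp_j[r])
      idk <- resolve(config$causal_pairs$snp_k[r])
      jj <- match(idj, panel$map$snp); kk <- match(idk, panel$map$snp)
      if (is.na(jj) || is.na(kk))
        stop("causal pair locus not in panel: ", idj, " / ", idk)
      cj <- xa_of_codes(panel$codes[cow_rows, jj])
      ck <- xa_of_codes(panel$codes[cow_rows, kk])
      aa <- config$causal_pairs$aa[r]
      g_val <- g_val + code_epistasis(cj$xa, ck$xa) * aa
      pair_tab <- rbind(pair_tab,
                        data.frame(snp_j = idj, snp_k = idk, aa = aa,
                                   stringsAsFactors = FALSE))
    }
  }
  hidden_tab <- NULL
  hc <- config$hidden_causal
  if (!is.null(hc)) {
    g_c <- geno$truth$hidden$genotype[match(cows, ped$animal)]
    p <- mean(g_c) / 2
    sigma_p2 <- config$sigma_g2 + config$sigma_pe2 + config$sigma_e2
    a <- if (!is.null(hc$a)) hc$a else {
      vf <- if (is.null(hc$var_frac)) 0.04 else hc$var_frac
      sqrt(vf * sigma_p2 / (2 * p * (1 - p)))
    }
    d <- if (is.null(hc$d)) 0 else hc$d
    g_val <- g_val + code_additive(g_c, p) * a +
      if (d != 0) code_dominance(g_c, p) * d else 0
    hidden_tab <- list(a = a, d = d, p = p,
                       var_a = 2 * p * (1 - p) * a^2,
                       tag_r2 = geno$truth$hidden$tag_r2,
                       genotype = stats::setNames(g_c, cows))
  }

  fx <- config$fixed_effects
  fx_levels <- lapply(fx, function(f)
    stats::setNames(stats::rnorm(f$n_levels, 0, f$sd),
                    paste0("L", seq_len(f$n_levels))))

  rr <- seq(config$records_range[1], config$records_range[2])
  k <- if (length(rr) == 1) rep(rr, length(cows)) else
    sample(rr, length(cows), replace = TRUE)
  animal <- rep(cows, k)
  n_rec <- length(animal)
  pe <- stats::setNames(stats::rnorm(length(cows), 0,
                                     sqrt(config$sigma_pe2)), cows)
  e <- stats::rnorm(n_rec, 0, sqrt(config$sigma_e2))
  lev <- lapply(names(fx), function(nm)
    sample(names(fx_levels[[nm]]), n_rec, replace = TRUE))
  names(lev) <- names(fx)
  fx_sum <- Reduce(`+`, lapply(names(fx),
                               function(nm) fx_levels[[nm]][lev[[nm]]]))
  value <- config$mu + fx_sum + g_val[animal] + u[animal] + pe[animal] + e

  pheno <- data.frame(animal = animal, value = as.numeric(value),
                      hys = factor(lev$hys), parity = factor(lev$parity),
                      age_class = factor(lev$age_class),
                      month = factor(lev$month), stringsAsFactors = FALSE)
  truth <- structure(list(
    causal = causal_tab, causal_pairs = pair_tab, hidden = hidden_tab,
    sigma_g2 = config$sigma_g2, sigma_pe2 = config$sigma_pe2,
    sigma_e2 = config$sigma_e2,
    sigma_p2 = config$sigma_g2 + config$sigma_pe2 + config$sigma_e2,
    breeding_values = u, fixed_effect_levels = fx_levels,
    cows = cows), class = "sim_truth")
  list(pheno = pheno, truth = truth)
}

#' Simulate a complete population
#'
#' Convenience wrapper: pedigree, genotypes, phenotypes and the
#' relationship matrix in one call.
#'
#' @param config a [sim_config()].
#' @return list: `config`, `ped`, `panel`, `pheno`, `truth`, `A`, `cows`,
#'   `pool` (base haplotypes, for sharing with a second population).
#' @export
simulate_population <- function(config) {
  ped <- simulate_pedigree(config)
  geno <- simulate_genotypes(ped, config)
  A <- build_A(ped)
  ph <- simulate_phenotypes(ped, geno, config, A = A)
  list(config = config, ped = ped, panel = geno$panel, pheno = ph$pheno,
       truth = ph$truth, A = A, cows = ph$truth$cows, pool = geno$pool)
}

#' Simulate two populations with partially shared haplotypes
#'
#' The second population's founder haplotype pool mixes a fraction
#' `pool_overlap` of the first population's pool with freshly drawn
#' haplotypes, so some causal variants segregate in both "breeds" and some
#' effectively in one — the structure needed to exercise cross-population
#' validation, including legitimate non-replication.
#'
#' @param config_a,config_b [sim_config()]s for the two populations; they
#'   must share the genome layout (`n_chrom`, `snps_per_chrom`,
#'   `chrom_length_bp`, `hidden_causal` geometry).
#' @param pool_overlap fraction of population B's pool copied from A's.
#' @return list with `a` and `b`, each a [simulate_population()] result.
#' @export
simulate_two_breeds <- function(config_a, config_b, pool_overlap = 0.5) {
  config_b$map_seed <- config_a$map_seed
  pop_a <- simulate_population(config_a)
  map_b <- sim_map(config_b)
  set.seed(derive_seed(config_b$seed, 7L))
  fresh <- make_pool(map_b, config_b)
  K <- config_b$n_hap_pool
  n_shared <- round(pool_overlap * K)
  config_b$pool <- lapply(seq_along(fresh), function(ch) {
    rbind(pop_a$pool[[ch]][seq_len(n_shared), , drop = FALSE],
          fresh[[ch]][seq_len(K - n_shared), , drop = FALSE])
  })
  pop_b <- simulate_population(config_b)
  list(a = pop_a, b = pop_b)
}

#' Write a simulated population to pipeline-readable files
#'
#' Emits `pedigree.csv`, `map.csv`, `genotypes.csv`, `phenotypes.csv` and
#' `truth.json` under `dir` — the same formats the ingest functions read.
#'
#' @param pop a [simulate_population()] result.
#' @param dir output directory (created if needed).
#' @export
write_sim_files <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped_df <- data.frame(animal = pop$ped$animal,
                       sire = ifelse(is.na(pop$ped$sire), "0", pop$ped$sire),
                       dam = ifelse(is.na(pop$ped$dam), "0", pop$ped$dam))
  utils::write.csv(ped_df, file.path(dir, "pedigree.csv"), row.names = FALSE)
  utils::write.csv(pop$panel$map, file.path(dir, "map.csv"),
                   row.names = FALSE)
  gdf <- data.frame(animal = pop$panel$animal, pop$panel$codes,
                    check.names = FALSE)
  utils::write.csv(gdf, file.path(dir, "genotypes.csv"), row.names = FALSE)
  utils::write.csv(pop$pheno, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  tr <- pop$truth
  tr$breeding_values <- as.list(tr$breeding_values)
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(dir)
}
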