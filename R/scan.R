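# Genome-wide additive and dominance scans: thresholds, the closed-form
# false discovery rate, per-SNP variance partitioning, region merging and
# Manhattan-ready output.

#' Bonferroni-corrected significance threshold
#'
#' `alpha / n_tests`, optionally rounded to the nearest power of ten
#' (`power10_rounding`), the convention under which 0.05 / 408,255 becomes
#' 1e-7.
#'
#' @param alpha nominal genome-wide error rate (default 0.05).
#' @param n_tests number of tests performed.
#' @param power10_rounding round the threshold to the nearest power of ten.
#' @return p-value threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests, power10_rounding = FALSE) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  thr <- alpha / n_tests
  if (power10_rounding) thr <- 10^round(log10(thr))
  thr
}

#' Closed-form percent false discovery rate of a scan threshold
#'
#' `%FDR = P (1 - S/T) / ((S/T) (1 - P)) x 100`, where `P` is the p-value
#' threshold, `S` the number of significant tests and `T` the total number
#' of tests. Values above 100% are possible and indicate fewer significant
#' results than expected by chance.
#'
#' @param p_threshold p-value threshold used to declare significance.
#' @param S number of significant tests at that threshold.
#' @param T_tests total number of tests.
#' @return percent FDR (may exceed 100); `NA` with a warning when `S = 0`.
#' @export
fdr_percent <- function(p_threshold, S, T_tests) {
  stopifnot(p_threshold > 0, p_threshold < 1, S >= 0, S <= T_tests)
  if (S == 0) {
    warning("no significant tests; FDR undefined")
    return(NA_real_)
  }
  r <- S / T_tests
  p_threshold * (1 - r) / (r * (1 - p_threshold)) * 100
}

#' Run a genome-wide additive or dominance scan
#'
#' Tests each SNP one at a time under the mixed model with the null-model
#' variance components. The additive variant fits `[1, x_a]` and tests
#' `a_j`; the dominance variant fits the joint model `[1, x_a, x_d]` and
#' tests `d_j`. SNPs with degenerate allele frequency or collinear/constant
#' covariates are flagged not-testable and excluded from the test count.
#'
#' @param panel a [genotype_panel()] restricted to the analysed population.
#' @param stats [allele_stats()] for the same population.
#' @param response data.frame from [residualize()] (`animal`, `residual`),
#'   or any data.frame with those columns.
#' @param vc null-model [variance_components()].
#' @param A numerator relationship matrix covering the response animals.
#' @param variant `"additive"` or `"dominance"`.
#' @param threshold significance threshold; default is the Bonferroni
#'   threshold for the number of testable SNPs.
#' @param alpha nominal rate for the default threshold.
#' @param power10_rounding see [bonferroni_threshold()].
#' @param mode SNP-fitting mode, see [fit_snp()].
#' @return object of class `"scan_result"`: list with `results` (one row
#'   per SNP: snp, chrom, pos, effect_name, estimate, se, p, neglog10p, maf,
#'   variant, testable, flags), `variant`, `threshold`, `n_tests`, `n_sig`,
#'   `fdr_percent`, `vc`.
#' @export
run_scan <- function(panel, stats, response, vc, A,
                     variant = c("additive", "dominance"),
                     threshold = NULL, alpha = 0.05, power10_rounding = FALSE,
                     mode = "fixed-vc") {
  variant <- match.arg(variant)
  y <- response$residual
  animal <- as.character(response$animal)
  keep <- animal %in% panel$animal
  y <- y[keep]; animal <- animal[keep]
  ctx <- mm_context(y, animal, A, vc)
  row_of <- match(animal, panel$animal)
  st <- stats[match(panel$map$snp, stats$snp), ]

  m <- nrow(panel$map)
  res <- data.frame(snp = panel$map$snp, chrom = panel$map$chrom,
                    pos = panel$map$pos,
                    effect_name = if (variant == "additive") "a_j" else "d_j",
                    estimate = NA_real_, se = NA_real_, p = NA_real_,
                    neglog10p = NA_real_, maf = st$maf, variant = variant,
                    testable = FALSE, flags = "", stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    pj <- st$p[j]
    if (is.na(pj) || pj <= 0 || pj >= 1) {
      res$flags[j] <- "degenerate-frequency"
      next
    }
    xa <- code_additive(panel$codes[, j], pj)[row_of]
    cov <- if (variant == "additive") {
      cbind(x_a = xa)
    } else {
      cbind(x_a = xa, x_d = code_dominance(panel$codes[, j], pj)[row_of])
    }
    focal <- if (variant == "additive") "x_a" else "x_d"
    fit <- fit_snp(y, animal, A, vc, cov, focal = focal, mode = mode,
                   context = if (mode == "fixed-vc") ctx else NULL)
    if (isTRUE(fit$testable[1])) {
      res$estimate[j] <- fit$estimate[1]
      res$se[j] <- fit$se[1]
      res$p[j] <- fit$p[1]
      res$neglog10p[j] <- -log10(fit$p[1])
      res$testable[j] <- TRUE
    } else {
      res$flags[j] <- fit$reason[1]
    }
  }
  n_tests <- sum(res$testable)
  if (is.null(threshold))
    threshold <- bonferroni_threshold(alpha, max(n_tests, 1L), power10_rounding)
  n_sig <- sum(res$p < threshold, na.rm = TRUE)
  fdr <- if (n_sig > 0)
    fdr_percent(threshold, n_sig, n_tests) else NA_real_
  structure(list(results = res, variant = variant, threshold = threshold,
                 n_tests = n_tests, n_sig = n_sig, fdr_percent = fdr,
                 vc = vc),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("%s scan: %d SNPs tested, %d significant at p < %.3g",
              x$variant, x$n_tests, x$n_sig, x$threshold))
  if (!is.na(x$fdr_percent))
    cat(sprintf(" (FDR %.0f%%)", x$fdr_percent))
  cat("\n")
  invisible(x)
}

#' Significant rows of a scan
#'
#' @param scan a [run_scan()] result.
#' @param threshold override the scan's stored threshold.
#' @return data.frame of significant, testable SNP rows.
#' @export
significant_snps <- function(scan, threshold = scan$threshold) {
  r <- scan$results
  r[r$testable & !is.na(r$p) & r$p < threshold, , drop = FALSE]
}

#' Per-SNP variance explained and phenotypic fraction
#'
#' Additive variance `2 p q a^2` or dominance variance `4 p^2 q^2 d^2`,
#' expressed as a percentage of the phenotypic variance
#' `sigma_p2 = sigma_g2 + sigma_pe2 + sigma_e2` from the null model.
#'
#' @param estimate effect estimate(s) on the corrected-covariate scale.
#' @param p A-allele frequency (vectorised).
#' @param vc null-model [variance_components()], or a single number taken as
#'   `sigma_p2`.
#' @param type `"additive"` or `"dominance"`.
#' @return data.frame `sigma2_snp`, `fraction_percent`.
#' @export
variance_fraction <- function(estimate, p, vc, type = c("additive", "dominance")) {
  type <- match.arg(type)
  sigma_p2 <- if (inherits(vc, "variance_components"))
    phenotypic_variance(vc) else as.numeric(vc)
  q <- 1 - p
  s2 <- if (type == "additive") 2 * p * q * estimate^2
        else 4 * p^2 * q^2 * estimate^2
  data.frame(sigma2_snp = s2, fraction_percent = 100 * s2 / sigma_p2)
}

#' Merge significant SNPs into regions
#'
#' Single-linkage merging of significant SNPs on the same chromosome within
#' `gap_bp` of each other. The region boundary is the min/max member
#' position; the top SNP has the smallest p-value, ties broken by smaller
#' position.
#'
#' @param significant data.frame of significant SNPs (needs `snp`, `chrom`,
#'   `pos`, `p`), e.g. from [significant_snps()].
#' @param gap_bp merge distance in bp (default 1 Mbp, the scale over which
#'   strong LD persists in these populations).
#' @return data.frame: `chrom`, `start_bp`, `end_bp`, `n_snps`, `top_snp`,
#'   `top_p`, `snps` (comma-separated member ids).
#' @export
merge_regions <- function(significant, gap_bp = 1e6) {
  if (!nrow(significant)) stop("no significant SNPs to merge")
  s <- significant[order(significant$chrom, significant$pos), , drop = FALSE]
  out <- list()
  for (ch in unique(s$chrom)) {
    sc <- s[s$chrom == ch, , drop = FALSE]
    brk <- c(0, cumsum(diff(sc$pos) > gap_bp))
    for (g in unique(brk)) {
      m <- sc[brk == g, , drop = FALSE]
      top <- m[order(m$p, m$pos), ][1, ]
      out[[length(out) + 1L]] <-
        data.frame(chrom = ch, start_bp = min(m$pos), end_bp = max(m$pos),
                   n_snps = nrow(m), top_snp = top$snp, top_p = top$p,
                   snps = paste(m$snp, collapse = ","),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write Manhattan-plot-ready TSV
#'
#' Emits `chrom, pos, snp, neglog10p, variant` for any plotting tool.
#'
#' @param scan a [run_scan()] result.
#' @param path output path.
#' @export
write_manhattan_tsv <- function(scan, path) {
  r <- scan$results[scan$results$testable, c("chrom", "pos", "snp",
                                             "neglog10p", "variant")]
  utils::write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scan summary as JSON
#'
#' Thresholds, test counts and FDR for a scan, for pipeline bookkeeping.
#'
#' @param scan a [run_scan()] result.
#' @param path output path.
#' @export
write_scan_summary <- function(scan, path) {
  jsonlite::write_json(
    list(variant = scan$variant, threshold = scan$threshold,
         n_tests = scan$n_tests, n_sig = scan$n_sig,
         fdr_percent = scan$fdr_percent),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
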