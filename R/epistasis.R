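# Pairwise additive x additive interaction screen over discovery hits, and
# the conditional re-test that adds a large-effect tag SNP to expose
# interaction signals created by haplotype LD with an untyped causal
# variant.

#' Select SNP pairs for the interaction screen
#'
#' All unordered pairs of SNPs whose additive test passed `threshold` in the
#' discovery scan: `n(n-1)/2` pairs, stored with the first member earlier in
#' map order.
#'
#' @param additive_scan a [run_scan()] additive result.
#' @param threshold discovery threshold; default the scan's stored one.
#' @return data.frame `snp_j`, `snp_k`; zero rows (with a warning) when
#'   fewer than two SNPs are significant.
#' @export
select_pairs <- function(additive_scan, threshold = additive_scan$threshold) {
  if (additive_scan$variant != "additive")
    stop("pair selection requires an additive scan")
  hits <- significant_snps(additive_scan, threshold)
  n <- nrow(hits)
  if (n < 2) {
    warning("fewer than two significant SNPs; no pairs to test")
    return(data.frame(snp_j = character(), snp_k = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- utils::combn(n, 2)
  data.frame(snp_j = hits$snp[idx[1, ]], snp_k = hits$snp[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Number of pairwise interactions tested for n significant SNPs
#'
#' @param n number of SNPs with significant additive effects.
#' @return `n (n - 1) / 2`.
#' @export
pair_count <- function(n) {
  stopifnot(n >= 0)
  n * (n - 1) / 2
}

#' Test one pairwise additive x additive interaction
#'
#' Fits `[1, x_a(j), x_a(k), x_a(j) * x_a(k)]` (plus the additive covariates
#' of any conditioning SNPs) under the mixed model and tests the interaction
#' coefficient. Collinear designs — including pairs in complete LD and
#' conditioning lists containing a pair member — are flagged not-testable.
#'
#' @param xa_j,xa_k additive covariates of the pair, aligned to records.
#' @param y,animal,A,vc as in [solve_mme()].
#' @param conditioning optional named list of additive covariates added to
#'   the fixed part.
#' @param context optional precomputed solver (see [solve_mme()]).
#' @return one-row data.frame: interaction `estimate`, `se`, `p`, plus
#'   `est_j`, `est_k` main-effect estimates from the same fit and
#'   `testable`/`reason`.
#' @export
test_pair <- function(xa_j, xa_k, y, animal, A, vc, conditioning = NULL,
                      context = NULL) {
  cov <- cbind(x_a_j = xa_j, x_a_k = xa_k,
               x_e = code_epistasis(xa_j, xa_k))
  if (!is.null(conditioning)) {
    cond <- do.call(cbind, conditioning)
    colnames(cond) <- paste0("cond_", names(conditioning))
    # a conditioning SNP collinear with a pair member makes the pair
    # untestable rather than silently unconditioned
    base <- cbind(1, xa_j, xa_k, cond)
    if (qr(base)$rank < ncol(base))
      return(data.frame(estimate = NA_real_, se = NA_real_, p = NA_real_,
                        est_j = NA_real_, est_k = NA_real_, testable = FALSE,
                        reason = "conditioning collinear with pair",
                        stringsAsFactors = FALSE))
    cov <- cbind(cov, cond)
  }
  fit <- solve_mme(y, animal, A, vc, cov,
                   focal = c("x_e", "x_a_j", "x_a_k"), context = context)
  ei <- match("x_e", fit$effect)
  data.frame(estimate = fit$estimate[ei], se = fit$se[ei], p = fit$p[ei],
             est_j = fit$estimate[match("x_a_j", fit$effect)],
             est_k = fit$estimate[match("x_a_k", fit$effect)],
             testable = fit$testable[ei], reason = fit$reason[ei],
             stringsAsFactors = FALSE)
}

#' Run the pairwise interaction screen
#'
#' @param pairs data.frame from [select_pairs()].
#' @param panel,stats population panel and [allele_stats()].
#' @param response data.frame with `animal`, `residual` (see
#'   [residualize()]).
#' @param vc,A as in [run_scan()].
#' @param conditioning optional character vector of SNP ids whose additive
#'   covariates are added to every fit.
#' @param threshold significance threshold for the pair tests; default
#'   Bonferroni `0.05 / n_pairs`.
#' @param alpha,power10_rounding see [bonferroni_threshold()].
#' @return object of class `"epistasis_result"`: list with `results` (per
#'   pair: ids, interaction estimate/se/p, main effects, flags), `threshold`,
#'   `n_tests`, `n_sig`, `fdr_percent`, `conditioning`.
#' @export
run_epistasis <- function(pairs, panel, stats, response, vc, A,
                          conditioning = NULL, threshold = NULL,
                          alpha = 0.05, power10_rounding = FALSE) {
  y <- response$residual
  animal <- as.character(response$animal)
  keep <- animal %in% panel$animal
  y <- y[keep]; animal <- animal[keep]
  ctx <- mm_context(y, animal, A, vc)
  row_of <- match(animal, panel$animal)

  xa_of <- function(snp) {
    j <- match(snp, panel$map$snp)
    if (is.na(j)) return(NULL)
    pj <- stats$p[match(snp, stats$snp)]
    if (is.na(pj) || pj <= 0 || pj >= 1) return(NULL)
    code_additive(panel$codes[, j], pj)[row_of]
  }
  cond_list <- NULL
  if (!is.null(conditioning)) {
    cond_list <- lapply(conditioning, xa_of)
    names(cond_list) <- conditioning
    bad <- vapply(cond_list, is.null, logical(1))
    if (any(bad))
      stop("conditioning SNP(s) absent or monomorphic: ",
           paste(conditioning[bad], collapse = ", "))
  }

  m <- nrow(pairs)
  res <- data.frame(snp_j = pairs$snp_j, snp_k = pairs$snp_k,
                    est_int = NA_real_, se_int = NA_real_, p_int = NA_real_,
                    est_j = NA_real_, est_k = NA_real_,
                    testable = FALSE, flags = "", stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    xj <- xa_of(pairs$snp_j[i]); xk <- xa_of(pairs$snp_k[i])
    if (is.null(xj) || is.null(xk)) {
      res$flags[i] <- "monomorphic-or-absent"
      next
    }
    fit <- test_pair(xj, xk, y, animal, A, vc, conditioning = cond_list,
                     context = ctx)
    if (isTRUE(fit$testable)) {
      res$est_int[i] <- fit$estimate; res$se_int[i] <- fit$se
      res$p_int[i] <- fit$p
      res$est_j[i] <- fit$est_j; res$est_k[i] <- fit$est_k
      res$testable[i] <- TRUE
    } else res$flags[i] <- fit$reason
  }
  n_tests <- sum(res$testable)
  if (is.null(threshold))
    threshold <- bonferroni_threshold(alpha, max(n_tests, 1L), power10_rounding)
  n_sig <- sum(res$p_int < threshold, na.rm = TRUE)
  fdr <- if (n_sig > 0) fdr_percent(threshold, n_sig, n_tests) else NA_real_
  structure(list(results = res, threshold = threshold, n_tests = n_tests,
                 n_sig = n_sig, fdr_percent = fdr,
                 conditioning = conditioning),
            class = "epistasis_result")
}

#' @export
print.epistasis_result <- function(x, ...) {
  cat(sprintf("epistasis screen: %d pairs tested, %d significant at p < %.3g",
              x$n_tests, x$n_sig, x$threshold))
  if (!is.null(x$conditioning))
    cat(" | conditioned on:", paste(x$conditioning, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Conditional re-test of significant interaction pairs
#'
#' Re-tests every significant pair with the additive covariate of a
#' designated large-effect tag SNP added to the model. Interactions that
#' were only proxying the tagged causal variant through haplotype
#' combinations lose significance.
#'
#' @param epi an [run_epistasis()] result.
#' @param tag_snp id of the conditioning SNP (e.g. the highest additive
#'   peak in the implicated region).
#' @param panel,stats,response,vc,A as in [run_epistasis()].
#' @param threshold significance threshold; default the one in `epi`.
#' @return data.frame comparing each originally significant pair before and
#'   after conditioning: `snp_j`, `snp_k`, `p_before`, `p_after`,
#'   `still_significant`, `flags`; attribute `"n_remaining"` gives the count
#'   still significant.
#' @export
conditional_rescan <- function(epi, tag_snp, panel, stats, response, vc, A,
                               threshold = epi$threshold) {
  sig <- epi$results[epi$results$testable & !is.na(epi$results$p_int) &
                       epi$results$p_int < threshold, , drop = FALSE]
  if (!nrow(sig)) {
    out <- data.frame(snp_j = character(), snp_k = character(),
                      p_before = numeric(), p_after = numeric(),
                      still_significant = logical(), flags = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_remaining") <- 0L
    return(out)
  }
  if (!tag_snp %in% panel$map$snp)
    stop("tag SNP not in panel: ", tag_snp)
  re <- run_epistasis(sig[, c("snp_j", "snp_k")], panel, stats, response,
                      vc, A, conditioning = tag_snp, threshold = threshold)
  out <- data.frame(snp_j = sig$snp_j, snp_k = sig$snp_k,
                    p_before = sig$p_int, p_after = re$results$p_int,
                    still_significant = re$results$testable &
                      !is.na(re$results$p_int) &
                      re$results$p_int < threshold,
                    flags = re$results$flags, stringsAsFactors = FALSE)
  attr(out, "n_remaining") <- sum(out$still_significant)
  out
}

#' Write the pairwise screen as TSV
#'
#' @param epi an [run_epistasis()] result.
#' @param path output path.
#' @param rescan optional [conditional_rescan()] table whose `p_after`
#'   column is joined on.
#' @export
write_pairs_tsv <- function(epi, path, rescan = NULL) {
  r <- epi$results
  if (!is.null(rescan)) {
    key <- paste(r$snp_j, r$snp_k)
    rk <- paste(rescan$snp_j, rescan$snp_k)
    r$p_int_conditioned <- rescan$p_after[match(key, rk)]
  }
  utils::write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
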