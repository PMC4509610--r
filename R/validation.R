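# Cross-population confirmation of discovery hits: individual SNP
# validation and 500 kb segment validation, with sign-concordance and
# stage FDR accounting.

#' Individual SNP validation across populations
#'
#' A discovery-significant SNP validates when its p-value in the validation
#' population falls below `v_threshold`. Sign concordance compares the
#' A-allele effect estimates in the two populations (each on its own
#' allele-frequency coding). The stage FDR uses the number of discovery hits
#' actually present and testable in the validation scan as `T`.
#'
#' @param discovery,validation [run_scan()] results of the same variant on
#'   overlapping SNP sets.
#' @param v_threshold validation p-value threshold (default 0.01).
#' @param d_threshold discovery threshold; default the one stored in
#'   `discovery`.
#' @return object of class `"validation_report"`: list with `table` (per
#'   discovery hit: `snp`, `chrom`, `pos`, `p_disc`, `est_disc`, `tested`,
#'   `p_valid`, `est_valid`, `validated`, `same_dir`), and `summary`
#'   (`S`, `T`, `fdr_percent`, `n_same_dir`, `mode`).
#' @export
validate_individual <- function(discovery, validation, v_threshold = 0.01,
                                d_threshold = discovery$threshold) {
  if (discovery$variant != validation$variant)
    stop("discovery and validation scans test different variants")
  hits <- significant_snps(discovery, d_threshold)
  if (!nrow(hits)) stop("no discovery hits to validate")
  vres <- validation$results
  i <- match(hits$snp, vres$snp)
  tested <- !is.na(i) & vres$testable[pmax(i, 1L)]
  p_valid <- ifelse(tested, vres$p[i], NA_real_)
  est_valid <- ifelse(tested, vres$estimate[i], NA_real_)
  validated <- tested & !is.na(p_valid) & p_valid < v_threshold
  same_dir <- ifelse(validated,
                     sign(hits$estimate) == sign(est_valid), NA)
  tab <- data.frame(snp = hits$snp, chrom = hits$chrom, pos = hits$pos,
                    p_disc = hits$p, est_disc = hits$estimate,
                    tested = tested, p_valid = p_valid,
                    est_valid = est_valid, validated = validated,
                    same_dir = same_dir, stringsAsFactors = FALSE)
  S <- sum(validated)
  T_tests <- sum(tested)
  fdr <- if (S > 0 && T_tests > 0)
    fdr_percent(v_threshold, S, T_tests) else NA_real_
  structure(list(table = tab,
                 summary = list(S = S, T = T_tests, fdr_percent = fdr,
                                n_same_dir = sum(same_dir, na.rm = TRUE),
                                n_not_tested = sum(!tested),
                                v_threshold = v_threshold,
                                mode = "individual")),
            class = "validation_report")
}

#' Segment validation across populations
#'
#' A discovery hit is segment-validated when at least one validation-
#' population SNP on the same chromosome within `window_bp` of it (symmetric
#' and inclusive) has `p < v_threshold`. The stage `S` counts distinct
#' significant validation SNPs falling in the union of windows; `T` counts
#' all distinct validation SNPs in that union (recorded in the summary since
#' the definition affects the stage FDR).
#'
#' @inheritParams validate_individual
#' @param window_bp half-window in bp on each side (default 500,000).
#' @return a `"validation_report"`; its `table` gains `match_snps`
#'   (comma-separated significant validation SNPs in the window).
#' @export
validate_segment <- function(discovery, validation, v_threshold = 0.01,
                             window_bp = 5e5,
                             d_threshold = discovery$threshold) {
  if (discovery$variant != validation$variant)
    stop("discovery and validation scans test different variants")
  hits <- significant_snps(discovery, d_threshold)
  if (!nrow(hits)) stop("no discovery hits to validate")
  vres <- validation$results
  vres <- vres[vres$testable, , drop = FALSE]
  in_any_window <- rep(FALSE, nrow(vres))
  match_snps <- character(nrow(hits))
  validated <- logical(nrow(hits))
  for (k in seq_len(nrow(hits))) {
    w <- vres$chrom == hits$chrom[k] &
      abs(vres$pos - hits$pos[k]) <= window_bp
    in_any_window <- in_any_window | w
    sig <- w & vres$p < v_threshold
    validated[k] <- any(sig)
    match_snps[k] <- paste(vres$snp[sig], collapse = ",")
  }
  tab <- data.frame(snp = hits$snp, chrom = hits$chrom, pos = hits$pos,
                    p_disc = hits$p, est_disc = hits$estimate,
                    validated = validated, match_snps = match_snps,
                    stringsAsFactors = FALSE)
  S <- sum(in_any_window & vres$p < v_threshold)
  T_tests <- sum(in_any_window)
  fdr <- if (S > 0 && T_tests > 0)
    fdr_percent(v_threshold, S, T_tests) else NA_real_
  structure(list(table = tab,
                 summary = list(S = S, T = T_tests, fdr_percent = fdr,
                                n_validated_hits = sum(validated),
                                v_threshold = v_threshold,
                                window_bp = window_bp,
                                T_definition = paste(
                                  "distinct validation SNPs in the union of",
                                  "discovery-hit windows"),
                                mode = "segment")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s validation: S = %d of T = %d at p < %g", s$mode, s$S, s$T,
              s$v_threshold))
  if (!is.na(s$fdr_percent)) cat(sprintf(" (FDR %.0f%%)", s$fdr_percent))
  if (!is.null(s$n_same_dir)) cat(";", s$n_same_dir, "same direction")
  cat("\n")
  invisible(x)
}

#' Write a validation report as TSV
#'
#' @param report a `"validation_report"`.
#' @param path output path.
#' @export
write_validation_tsv <- function(report, path) {
  utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
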