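# Genotype panels, allele statistics and the allele-frequency-corrected
# additive / dominance / interaction covariates.

#' Construct a genotype panel
#'
#' @param codes integer matrix, animals x SNPs, entries 0/1/2 = copies of the
#'   A allele (aa, Aa, AA) or `NA` for missing. Row names are animal ids.
#' @param map data.frame with columns `snp`, `chrom`, `pos` (1-based bp).
#'   SNPs are sorted within chromosome by position; the code matrix columns
#'   are reordered to match.
#' @return Object of class `"genotype_panel"`: list with `codes`, `map`,
#'   `animal`.
#' @export
genotype_panel <- function(codes, map) {
  codes <- as.matrix(codes)
  map <- as.data.frame(map)
  stopifnot(all(c("snp", "chrom", "pos") %in% names(map)))
  map$snp <- as.character(map$snp)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (nrow(map) != ncol(codes))
    stop("map rows (", nrow(map), ") != genotype columns (", ncol(codes), ")")
  dup <- map$snp[duplicated(map$snp)]
  if (length(dup))
    stop("duplicate snp id(s): ", paste(unique(dup), collapse = ", "))
  if (any(is.na(map$pos)) || any(map$pos <= 0L))
    stop("positions must be strictly positive integers")
  bad <- !(codes %in% c(0L, 1L, 2L) | is.na(codes))
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or missing; found: ",
         paste(unique(codes[bad]), collapse = ", "))
  if (is.null(rownames(codes)))
    rownames(codes) <- paste0("ind", seq_len(nrow(codes)))
  ord <- order(map$chrom, map$pos, map$snp)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  codes <- codes[, ord, drop = FALSE]
  colnames(codes) <- map$snp
  structure(list(codes = codes, map = map, animal = rownames(codes)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$codes), "animals x", ncol(x$codes),
      "SNPs on", length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read genotypes from PLINK .raw / .map or paired CSVs
#'
#' For `dialect = "plink-raw"`, `path` is the .raw file (header `FID IID PAT
#' MAT SEX PHENOTYPE` then one allele-count column per SNP) and `map_path`
#' the 4-column .map (`chrom snp cm pos`). For `dialect = "csv"`, `path` is a
#' matrix CSV whose first column is the animal id and remaining columns are
#' SNP codes, and `map_path` a CSV with columns `snp,chrom,pos`.
#'
#' @param path genotype matrix file.
#' @param map_path map file.
#' @param dialect `"plink-raw"` or `"csv"`.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, map_path, dialect = c("plink-raw", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "plink-raw") {
    raw <- utils::read.table(path, header = TRUE, check.names = FALSE)
    if (ncol(raw) < 7)
      stop("PLINK .raw file must have >= 7 columns")
    codes <- as.matrix(raw[, -(1:6), drop = FALSE])
    rownames(codes) <- as.character(raw$IID)
    # .raw columns are SNP_<counted allele>; strip the allele suffix
    colnames(codes) <- sub("_[ACGT0-9]+$", "", colnames(codes))
    map <- utils::read.table(map_path, header = FALSE,
                             col.names = c("chrom", "snp", "cm", "pos"),
                             colClasses = c("character", "character",
                                            "numeric", "integer"))
    map <- map[, c("snp", "chrom", "pos")]
  } else {
    mat <- utils::read.csv(path, check.names = FALSE)
    codes <- as.matrix(mat[, -1, drop = FALSE])
    rownames(codes) <- as.character(mat[[1]])
    map <- utils::read.csv(map_path, colClasses = c("character"))
    map$pos <- as.integer(map$pos)
  }
  miss <- setdiff(colnames(codes), map$snp)
  if (length(miss))
    stop("SNPs in matrix missing from map: ", paste(miss, collapse = ", "))
  map <- map[match(colnames(codes), map$snp), , drop = FALSE]
  genotype_panel(codes, map)
}

#' Per-SNP allele and genotype-class statistics
#'
#' The frequency of the A allele is `p = (2 n_AA + n_Aa) / (2 n_called)`;
#' genotype-class frequencies are taken over called animals only.
#'
#' @param panel a [genotype_panel()].
#' @return data.frame with one row per SNP: `snp`, `p`, `q`, `f_aa`, `f_Aa`,
#'   `f_AA`, `maf`, `min_class_freq`, `n_called`, `all_missing`.
#' @export
allele_stats <- function(panel) {
  codes <- panel$codes
  n_called <- colSums(!is.na(codes))
  n_AA <- colSums(codes == 2L, na.rm = TRUE)
  n_Aa <- colSums(codes == 1L, na.rm = TRUE)
  n_aa <- colSums(codes == 0L, na.rm = TRUE)
  p <- ifelse(n_called > 0, (2 * n_AA + n_Aa) / (2 * n_called), NA_real_)
  f_aa <- ifelse(n_called > 0, n_aa / n_called, NA_real_)
  f_Aa <- ifelse(n_called > 0, n_Aa / n_called, NA_real_)
  f_AA <- ifelse(n_called > 0, n_AA / n_called, NA_real_)
  all_missing <- n_called == 0L
  if (any(all_missing))
    warning(sum(all_missing), " SNP(s) with no called genotypes; ",
            "excluded downstream")
  data.frame(snp = panel$map$snp, p = p, q = 1 - p,
             f_aa = f_aa, f_Aa = f_Aa, f_AA = f_AA,
             maf = pmin(p, 1 - p),
             min_class_freq = pmin(f_aa, f_Aa, f_AA),
             n_called = as.integer(n_called),
             all_missing = all_missing,
             stringsAsFactors = FALSE)
}

#' Filter SNPs on minor genotype-class frequency
#'
#' A SNP is removed when the frequency of its rarest genotype class falls
#' below `min_class_freq` in any of the populations supplied — this
#' guarantees enough observations in all three genotype classes for the
#' dominance coding in every analysed population. All-missing SNPs are always
#' removed.
#'
#' @param panel a [genotype_panel()].
#' @param stats a single [allele_stats()] data.frame or a named list of them
#'   (one per population).
#' @param min_class_freq threshold, in (0, 1/3].
#' @return list with `panel` (retained SNPs) and `report` (data.frame: one
#'   row per SNP x population with `minor_class_freq` and `removed`), plus
#'   `n_total`, `n_removed`, `n_retained`.
#' @export
filter_by_genotype_class <- function(panel, stats, min_class_freq = 0.01) {
  if (min_class_freq <= 0 || min_class_freq > 1 / 3)
    stop("min_class_freq must be in (0, 1/3]")
  if (is.data.frame(stats)) stats <- list(population = stats)
  if (is.null(names(stats)))
    names(stats) <- paste0("pop", seq_along(stats))
  snps <- panel$map$snp
  removed <- rep(FALSE, length(snps))
  report <- do.call(rbind, lapply(names(stats), function(nm) {
    st <- stats[[nm]][match(snps, stats[[nm]]$snp), , drop = FALSE]
    fail <- is.na(st$min_class_freq) | st$min_class_freq < min_class_freq
    removed <<- removed | fail
    data.frame(snp = snps, population = nm,
               minor_class_freq = st$min_class_freq,
               removed = fail, stringsAsFactors = FALSE)
  }))
  if (all(removed)) stop("no SNPs survive the genotype-class filter")
  keep <- which(!removed)
  out <- genotype_panel(panel$codes[, keep, drop = FALSE],
                        panel$map[keep, , drop = FALSE])
  list(panel = out, report = report,
       n_total = length(snps),
       n_removed = sum(removed),
       n_retained = panel_retained(length(snps), sum(removed)))
}

#' Retained-SNP bookkeeping
#'
#' Number of SNPs kept for analysis after the genotype-class filter.
#'
#' @param n_total SNPs before filtering.
#' @param n_removed SNPs removed.
#' @return `n_total - n_removed`.
#' @export
panel_retained <- function(n_total, n_removed) {
  stopifnot(n_removed >= 0, n_removed <= n_total)
  as.integer(n_total) - as.integer(n_removed)
}

#' Allele-frequency-corrected additive covariate
#'
#' Maps genotype codes 0/1/2 (aa, Aa, AA) to `{-2p, q - p, 2q}` where `p` is
#' the frequency of the A allele in the analysed population. Missing codes
#' are imputed to the mean of the coded values over called animals, so they
#' carry no information.
#'
#' @param codes integer vector of 0/1/2/NA genotype codes.
#' @param p frequency of the A allele, strictly inside (0, 1).
#' @return numeric covariate vector.
#' @export
code_additive <- function(codes, p) {
  if (is.na(p) || p <= 0 || p >= 1)
    stop("degenerate SNP: allele frequency p must be strictly in (0, 1)")
  q <- 1 - p
  x <- c(-2 * p, q - p, 2 * q)[codes + 1L]
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  x
}

#' Allele-frequency-corrected dominance covariate
#'
#' Maps genotype codes 0/1/2 (aa, Aa, AA) to `{-2p^2, 2pq, -2q^2}`. Missing
#' codes are imputed to the mean as in [code_additive()].
#'
#' @inheritParams code_additive
#' @return numeric covariate vector.
#' @export
code_dominance <- function(codes, p) {
  if (is.na(p) || p <= 0 || p >= 1)
    stop("degenerate SNP: allele frequency p must be strictly in (0, 1)")
  q <- 1 - p
  x <- c(-2 * p^2, 2 * p * q, -2 * q^2)[codes + 1L]
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  x
}

#' Pairwise additive-by-additive interaction covariate
#'
#' Elementwise product of the two additive covariates. Note that for two
#' SNPs in complete LD this product collapses onto the square of the shared
#' additive covariate and is collinear with the dominance contrast — the
#' model-fitting layer flags such pairs as not testable.
#'
#' @param xa_j,xa_k additive covariates from [code_additive()].
#' @return numeric covariate vector.
#' @export
code_epistasis <- function(xa_j, xa_k) {
  if (length(xa_j) != length(xa_k))
    stop("interaction covariates must have equal length")
  xa_j * xa_k
}

#' Covariate matrix for a panel
#'
#' Applies [code_additive()] or [code_dominance()] column-wise. SNPs with
#' degenerate frequency (p of 0 or 1, or all-missing) yield `NA` columns.
#'
#' @param panel a [genotype_panel()].
#' @param stats matching [allele_stats()].
#' @param type `"additive"` or `"dominance"`.
#' @return numeric matrix, animals x SNPs.
#' @export
code_panel <- function(panel, stats, type = c("additive", "dominance")) {
  type <- match.arg(type)
  coder <- if (type == "additive") code_additive else code_dominance
  st <- stats[match(panel$map$snp, stats$snp), ]
  out <- matrix(NA_real_, nrow(panel$codes), ncol(panel$codes),
                dimnames = dimnames(panel$codes))
  ok <- which(!is.na(st$p) & st$p > 0 & st$p < 1)
  for (j in ok) out[, j] <- coder(panel$codes[, j], st$p[j])
  out
}

#' Write the genotype-class filter report as TSV
#'
#' @param report `report` element from [filter_by_genotype_class()].
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
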