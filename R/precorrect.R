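# Pre-correction of repeated phenotype records for fixed effects.
# The residuals from an OLS fit on the full recorded population become the
# response used by the genome scans (genotyped animals only).

#' Read a phenotype table
#'
#' @param path CSV with columns `animal,value,hys,parity,age_class,month`
#'   (herd-year-season, parity, age-at-calving class, month-of-calving).
#' @return data.frame with factor columns; animals may repeat.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "value", "hys", "parity", "age_class", "month")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype file missing column(s): ", paste(miss, collapse = ", "))
  df$animal <- as.character(df$animal)
  for (f in c("hys", "parity", "age_class", "month"))
    df[[f]] <- factor(df[[f]])
  df
}

#' Fit the fixed-effect pre-correction model
#'
#' Ordinary least squares of the trait on herd-year-season, parity,
#' age-at-calving class and month of calving, fitted on the full set of
#' records (not just the genotyped animals).
#'
#' @param table phenotype data.frame (see [read_phenotypes()]).
#' @param formula model formula; the default uses all four factors.
#' @return Object of class `"precorrect_fit"` wrapping the `lm` fit.
#' @export
fit_fixed_effects <- function(table,
                              formula = value ~ hys + parity + age_class + month) {
  vars <- all.vars(formula)[-1]
  for (v in vars) {
    if (!v %in% names(table)) stop("missing model variable: ", v)
    if (is.factor(table[[v]]) && nlevels(droplevels(table[[v]])) < 2 &&
        length(vars) > 1)
      warning("factor '", v, "' has a single level with records; it is ",
              "absorbed by the intercept")
  }
  fit <- stats::lm(formula, data = table)
  alias <- is.na(stats::coef(fit))
  if (any(alias))
    stop("fixed-effect design is rank deficient after constraints; ",
         "confounded terms: ",
         paste(names(stats::coef(fit))[alias], collapse = ", "))
  structure(list(fit = fit, formula = formula,
                 sigma2 = summary(fit)$sigma^2),
            class = "precorrect_fit")
}

#' @export
print.precorrect_fit <- function(x, ...) {
  cat("fixed-effect pre-correction:",
      deparse(x$formula), "\n  residual variance:",
      format(x$sigma2, digits = 4), "on",
      x$fit$df.residual, "df\n")
  invisible(x)
}

#' Residualize records against a fitted pre-correction model
#'
#' Residual = observed - fitted, computed for every record. When `animals`
#' is supplied (the genotyped set), only those animals' records are
#' returned — records without both genotype and phenotype are discarded.
#'
#' @param table phenotype data.frame; factor levels must all have been seen
#'   by the fit.
#' @param model a [fit_fixed_effects()] result.
#' @param animals optional character vector restricting the output.
#' @return data.frame `animal`, `record_index`, `residual`.
#' @export
residualize <- function(table, model, animals = NULL) {
  for (v in all.vars(model$formula)[-1]) {
    if (is.factor(table[[v]])) {
      seen <- levels(model$fit$model[[v]])
      new <- setdiff(levels(droplevels(table[[v]])), seen)
      if (length(new))
        stop("factor '", v, "' has level(s) unseen at fitting: ",
             paste(new, collapse = ", "))
      table[[v]] <- factor(table[[v]], levels = seen)
    }
  }
  fitted <- stats::predict(model$fit, newdata = table)
  out <- data.frame(animal = table$animal,
                    record_index = stats::ave(seq_len(nrow(table)),
                                              table$animal,
                                              FUN = seq_along),
                    residual = table$value - fitted,
                    stringsAsFactors = FALSE)
  if (!is.null(animals)) out <- out[out$animal %in% animals, , drop = FALSE]
  rownames(out) <- NULL
  out
}
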