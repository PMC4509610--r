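# The statistical engine: y = 1 mu + X b + Z u + W pe + e with
# u ~ N(0, A sg2), pe ~ N(0, I spe2), e ~ N(0, I se2).
# Z and W both map records to animals; V = Z(A sg2 + I spe2)Z' + I se2.
# All V^{-1} products use the Woodbury identity at animal-level cost:
#   V^{-1} = I/se2 - Z M^{-1} Z' / se2^2,   M = G^{-1} + D/se2,
# with G = A sg2 + I spe2 (q x q) and D = diag(records per animal), so no
# record-level n x n matrix is ever formed.

#' Variance components container
#'
#' @param sigma_g2 polygenic additive variance.
#' @param sigma_pe2 permanent-environment variance.
#' @param sigma_e2 residual variance.
#' @param loglik REML log-likelihood at convergence (optional).
#' @param ... further bookkeeping fields (iterations, converged, ...).
#' @return object of class `"variance_components"`.
#' @export
variance_components <- function(sigma_g2, sigma_pe2, sigma_e2,
                                loglik = NA_real_, ...) {
  stopifnot(sigma_g2 >= 0, sigma_pe2 >= 0, sigma_e2 >= 0)
  structure(list(sigma_g2 = sigma_g2, sigma_pe2 = sigma_pe2,
                 sigma_e2 = sigma_e2, loglik = loglik, ...),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance components (REML):\n")
  cat(sprintf("  polygenic  sigma_g2  = %.6g\n", x$sigma_g2))
  cat(sprintf("  perm. env. sigma_pe2 = %.6g\n", x$sigma_pe2))
  cat(sprintf("  residual   sigma_e2  = %.6g\n", x$sigma_e2))
  cat(sprintf("  phenotypic sigma_p2  = %.6g\n", phenotypic_variance(x)))
  if (!is.na(x$loglik))
    cat(sprintf("  log-likelihood %.4f (%s in %d iterations)\n", x$loglik,
                if (isTRUE(x$converged)) "converged" else "NOT converged",
                if (is.null(x$iterations)) NA_integer_ else x$iterations))
  invisible(x)
}

#' Total phenotypic variance sigma_g2 + sigma_pe2 + sigma_e2
#' @param vc a [variance_components()] object.
#' @export
phenotypic_variance <- function(vc) {
  vc$sigma_g2 + vc$sigma_pe2 + vc$sigma_e2
}

# Build the Woodbury solver for V given components and record structure.
# y-length objects are records; `animal` maps each record to a row of A.
mm_context <- function(y, animal, A, vc) {
  animal <- as.character(animal)
  ids <- unique(animal)
  miss <- setdiff(ids, rownames(A))
  if (length(miss))
    stop("animals with records but absent from relationship matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  Asub <- A[ids, ids, drop = FALSE]
  aidx <- match(animal, ids)
  n <- length(y)
  q <- length(ids)
  d <- tabulate(aidx, q)
  se2 <- vc$sigma_e2
  if (se2 <= 0) stop("residual variance must be positive")
  sg2 <- max(vc$sigma_g2, 0)
  spe2 <- max(vc$sigma_pe2, 0)

  if (sg2 == 0 && spe2 == 0) {
    vsolve <- function(x) x / se2
    logdetV <- n * log(se2)
    Minv <- NULL
  } else {
    G <- sg2 * Asub
    diag(G) <- diag(G) + spe2
    cG <- chol(G)
    Ginv <- chol2inv(cG)
    M <- Ginv
    diag(M) <- diag(M) + d / se2
    cM <- chol(M)
    Minv <- chol2inv(cM)
    logdetV <- n * log(se2) + 2 * sum(log(diag(cG))) + 2 * sum(log(diag(cM)))
    vsolve <- function(x) {
      x <- as.matrix(x)
      t <- rowsum(x, aidx, reorder = TRUE)
      (x - (Minv %*% t)[aidx, , drop = FALSE] / se2) / se2
    }
  }
  list(y = y, aidx = aidx, ids = ids, A = Asub, d = d, n = n, q = q,
       vc = list(sigma_g2 = sg2, sigma_pe2 = spe2, sigma_e2 = se2),
       vsolve = vsolve, logdetV = logdetV, Minv = Minv)
}

# REML log-likelihood + gradient + average-information matrix at theta,
# for the active components listed in `act` (subset of c("g","pe","e")).
reml_state <- function(theta, y, animal, A, X, act) {
  vc <- list(sigma_g2 = theta[["g"]], sigma_pe2 = theta[["pe"]],
             sigma_e2 = theta[["e"]])
  ctx <- mm_context(y, animal, A, vc)
  n <- ctx$n
  a <- 1 / vc$sigma_e2
  ViX <- ctx$vsolve(X)
  Viy <- ctx$vsolve(y)
  XtViX <- crossprod(X, ViX)
  C <- solve(XtViX)
  XtViy <- crossprod(X, Viy)
  Py <- Viy - ViX %*% (C %*% XtViy)
  yPy <- sum(y * Py)
  ll <- -0.5 * (ctx$logdetV + determinant(XtViX, logarithm = TRUE)$modulus +
                  yPy)

  # traces via Z'PZ (q x q)
  if (is.null(ctx$Minv)) {
    ZtViZ <- diag(a * ctx$d, ctx$q)
  } else {
    ZtViZ <- -a^2 * ctx$Minv * outer(ctx$d, ctx$d)
    diag(ZtViZ) <- diag(ZtViZ) + a * ctx$d
  }
  ZtViX <- rowsum(ViX, ctx$aidx, reorder = TRUE)
  ZtPZ <- ZtViZ - ZtViX %*% C %*% t(ZtViX)
  tr_Vinv <- a * n - if (is.null(ctx$Minv)) 0 else
    a^2 * sum(diag(ctx$Minv) * ctx$d)
  tr_P <- tr_Vinv - sum(C * crossprod(ViX))
  tPV <- c(g = sum(ctx$A * ZtPZ), pe = sum(diag(ZtPZ)), e = tr_P)

  t1 <- rowsum(as.matrix(Py), ctx$aidx, reorder = TRUE)[, 1]
  At1 <- as.vector(ctx$A %*% t1)
  yPVPy <- c(g = sum(t1 * At1), pe = sum(t1 * t1), e = sum(Py * Py))
  grad <- -0.5 * (tPV[act] - yPVPy[act])

  # average information: 0.5 F' P F with F = [V_g Py, V_pe Py, V_e Py]
  Fm <- cbind(g = At1[ctx$aidx], pe = t1[ctx$aidx], e = as.vector(Py))
  Fm <- Fm[, act, drop = FALSE]
  ViF <- ctx$vsolve(Fm)
  PF <- ViF - ViX %*% (C %*% crossprod(X, ViF))
  AI <- 0.5 * crossprod(Fm, PF)

  list(ll = as.numeric(ll), grad = grad, AI = AI, ctx = ctx)
}

#' REML variance components for the null (no-SNP) model
#'
#' Average-information REML with step-halving and an EM fallback for the
#' model `y = X beta + Z u + W pe + e` (default `X` is the intercept only,
#' matching a pre-corrected response). Components are constrained
#' non-negative by projection to a small floor; convergence requires both the
#' log-likelihood change and the relative parameter change to fall below
#' `tol`.
#'
#' @param y numeric response, one entry per record.
#' @param animal character vector mapping records to animals (rownames of
#'   `A`).
#' @param A numerator relationship matrix covering all animals with records.
#' @param X optional fixed-effect design matrix (default: intercept).
#' @param start optional starting values `c(sigma_g2, sigma_pe2, sigma_e2)`.
#' @param tol convergence tolerance (default `1e-6`).
#' @param max_iter iteration cap; exceeding it is an error with a trace.
#' @return a [variance_components()] with `loglik`, `converged`,
#'   `iterations`, and `ai_rcond` (reciprocal condition number of the final
#'   average-information matrix; tiny values signal weak identifiability).
#' @export
reml_null <- function(y, animal, A, X = NULL, start = NULL,
                      tol = 1e-6, max_iter = 100L) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  vary <- stats::var(y)
  if (!is.finite(vary) || vary <= .Machine$double.eps * 100) {
    return(variance_components(0, 0, 0, loglik = NA_real_,
                               converged = TRUE, iterations = 0L,
                               note = "zero-variance response"))
  }
  d <- table(animal)
  act <- c("g", "pe", "e")
  pe_fixed_zero <- FALSE
  if (!any(d > 1)) {
    warning("no animal has repeated records; sigma_pe2 is not identifiable ",
            "and is fixed at 0")
    act <- c("g", "e")
    pe_fixed_zero <- TRUE
  }
  floor_ <- 1e-8 * vary
  theta <- c(g = 0.3 * vary, pe = if (pe_fixed_zero) 0 else 0.1 * vary,
             e = 0.6 * vary)
  if (!is.null(start)) theta[c("g", "pe", "e")] <- pmax(start, 0)
  if (pe_fixed_zero) theta[["pe"]] <- 0
  theta[act] <- pmax(theta[act], floor_)

  st <- reml_state(theta, y, animal, A, X, act)
  trace_ll <- st$ll
  converged <- FALSE
  iter <- 0L
  ai_rcond <- NA_real_
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(st$AI, st$grad), error = function(e) NULL)
    ai_rcond <- tryCatch(rcond(st$AI), error = function(e) 0)
    # EM-REML update theta + (theta^2/n_i)(yPV_iPy - tr(PV_i)); the bracket
    # equals 2*grad, guaranteeing an ascent direction as fallback
    nn <- c(g = length(unique(animal)), pe = length(unique(animal)), e = n)
    em_step <- (theta[act]^2 / nn[act]) * (2 * st$grad)
    improved <- FALSE
    for (try_step in c(if (!is.null(step)) list(step), list(em_step))) {
      h <- 1
      for (k in 1:12) {
        cand <- theta
        cand[act] <- pmax(theta[act] + h * try_step, floor_)
        st_new <- tryCatch(reml_state(cand, y, animal, A, X, act),
                           error = function(e) NULL)
        if (!is.null(st_new) && is.finite(st_new$ll) &&
            st_new$ll >= st$ll - 1e-10) {
          dll <- st_new$ll - st$ll
          relpar <- max(abs(cand[act] - theta[act]) /
                          pmax(abs(theta[act]), 1e-3 * vary))
          theta <- cand; st <- st_new
          trace_ll <- c(trace_ll, st$ll)
          improved <- TRUE
          if (dll < tol && relpar < tol) converged <- TRUE
          break
        }
        h <- h / 2
      }
      if (improved) break
    }
    if (!improved || converged) break
  }
  if (!converged && iter >= max_iter)
    stop("REML did not converge in ", max_iter,
         " iterations; log-likelihood trace: ",
         paste(sprintf("%.4f", utils::tail(trace_ll, 8)), collapse = " -> "))
  if (ai_rcond < 1e-10 && is.finite(ai_rcond))
    warning("average-information matrix is near-singular (rcond = ",
            format(ai_rcond, digits = 3),
            "); variance components are weakly identifiable")
  zap <- function(v) if (v <= 2 * floor_) 0 else v
  variance_components(zap(theta[["g"]]),
                      if (pe_fixed_zero) 0 else zap(theta[["pe"]]),
                      theta[["e"]],
                      loglik = st$ll, converged = converged,
                      iterations = iter, ai_rcond = ai_rcond)
}

#' Solve the mixed-model equations for fixed effects given variance
#' components
#'
#' Generalized least squares `b = (X' V^{-1} X)^{-1} X' V^{-1} y` with
#' standard errors from the inverse coefficient matrix and a two-sided Wald
#' F test (1 numerator df) on each focal effect; denominator df is
#' `n_records - rank(fixed design)`.
#'
#' @param y numeric response per record.
#' @param animal record-to-animal map.
#' @param A numerator relationship matrix.
#' @param vc a [variance_components()].
#' @param covariates numeric matrix (records x effects) of named SNP
#'   covariates; an intercept is added automatically.
#' @param focal names of the covariates to test (default: all).
#' @param context optional precomputed solver from a previous call with the
#'   same `y`/`animal`/`A`/`vc` (used by the scan loop).
#' @return data.frame: `effect`, `estimate`, `se`, `p`, `df`, `testable`.
#' @export
solve_mme <- function(y, animal, A, vc, covariates,
                      focal = colnames(covariates), context = NULL) {
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("b", seq_len(ncol(covariates)))
  if (is.null(context)) context <- mm_context(y, animal, A, vc)
  X <- cbind(`(Intercept)` = 1, covariates)

  not_testable <- function(why) {
    data.frame(effect = focal, estimate = NA_real_, se = NA_real_,
               p = NA_real_, df = NA_real_, testable = FALSE,
               reason = why, stringsAsFactors = FALSE)
  }
  # collinearity / constant-covariate guard
  qrX <- qr(scale(X, center = FALSE,
                  scale = pmax(sqrt(colSums(X^2)), .Machine$double.eps)))
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    if (any(focal %in% dropped) || "(Intercept)" %in% dropped)
      return(not_testable("collinear or constant covariate"))
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  }
  sds <- apply(X[, focal, drop = FALSE], 2, stats::sd)
  if (any(sds < .Machine$double.eps^0.5))
    return(not_testable("constant focal covariate"))

  ViX <- context$vsolve(X)
  XtViX <- crossprod(X, ViX)
  C <- tryCatch(solve(XtViX), error = function(e) NULL)
  if (is.null(C)) return(not_testable("singular coefficient matrix"))
  b <- as.vector(C %*% crossprod(X, context$vsolve(y)))
  names(b) <- colnames(X)
  se <- sqrt(pmax(diag(C), 0))
  names(se) <- colnames(X)
  df2 <- context$n - ncol(X)
  Fstat <- (b[focal] / se[focal])^2
  p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  data.frame(effect = focal, estimate = b[focal], se = se[focal],
             p = as.numeric(p), df = df2, testable = TRUE,
             reason = "", row.names = NULL, stringsAsFactors = FALSE)
}

#' Test one SNP (or SNP pair) model
#'
#' Single-SNP regression under the mixed model. `mode = "fixed-vc"` reuses
#' the null-model variance components for every SNP; `mode = "per-snp-reml"`
#' re-estimates the components with the SNP covariates in the fixed part
#' before solving, mirroring a full per-SNP REML fit.
#'
#' @inheritParams solve_mme
#' @param mode `"fixed-vc"` or `"per-snp-reml"`.
#' @param ... passed to [reml_null()] in `per-snp-reml` mode.
#' @return as [solve_mme()], plus attribute `"vc"` (the components used).
#' @export
fit_snp <- function(y, animal, A, vc, covariates,
                    focal = colnames(covariates),
                    mode = c("fixed-vc", "per-snp-reml"),
                    context = NULL, ...) {
  mode <- match.arg(mode)
  covariates <- as.matrix(covariates)
  if (mode == "per-snp-reml") {
    X <- cbind(`(Intercept)` = 1, covariates)
    ok <- qr(X)$rank == ncol(X)
    if (ok) {
      vc <- reml_null(y, animal, A, X = X,
                      start = c(vc$sigma_g2, vc$sigma_pe2, vc$sigma_e2), ...)
      context <- NULL
    }
  }
  out <- solve_mme(y, animal, A, vc, covariates, focal, context = context)
  attr(out, "vc") <- vc
  out
}
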