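# REML for the additive + dominance GBLUP model
#   y = X beta + a + d + e,  Cov(a) = G sigma2_a,  Cov(d) = D sigma2_d,
#   Cov(e) = I sigma2_e.
#
# The residual variance is profiled out analytically, leaving a 2-D
# derivative-free search over the log variance ratios gamma_a = sigma2_a /
# sigma2_e and gamma_d = sigma2_d / sigma2_e. The REML log-likelihood
# includes the log|X'X| correction so that it is invariant to full-rank
# reparameterizations of the fixed effects.

#' Restricted log-likelihood of the additive-dominance mixed model
#'
#' @param sigma2 numeric vector `c(sigma2_a, sigma2_d, sigma2_e)`
#'   (`sigma2_d` ignored when `D` is `NULL`, in which case a length-2 vector
#'   `c(sigma2_a, sigma2_e)` is also accepted).
#' @param y numeric response vector.
#' @param X full-column-rank fixed-effects design matrix.
#' @param G additive relationship matrix.
#' @param D optional dominance relationship matrix.
#' @return the REML log-likelihood (a scalar).
#' @export
reml_loglik <- function(sigma2, y, X, G, D = NULL) {
  n <- length(y)
  p <- ncol(X)
  if (is.null(D)) {
    if (length(sigma2) == 3L) sigma2 <- sigma2[c(1L, 3L)]
    V <- sigma2[1L] * unclass(G) + diag(sigma2[2L], n)
  } else {
    V <- sigma2[1L] * unclass(G) + sigma2[2L] * unclass(D) +
      diag(sigma2[3L], n)
  }
  cV <- chol(V)
  Z <- backsolve(cV, cbind(y, X), transpose = TRUE)  # L^-1 [y X]
  zy <- Z[, 1L]
  ZX <- Z[, -1L, drop = FALSE]
  XtViX <- crossprod(ZX)
  cXtViX <- chol(XtViX)
  b <- backsolve(cXtViX, backsolve(cXtViX, crossprod(ZX, zy),
                                   transpose = TRUE))
  ytPy <- sum(zy^2) - drop(crossprod(crossprod(ZX, zy), b))
  logdet_V <- 2 * sum(log(diag(cV)))
  logdet_XtViX <- 2 * sum(log(diag(cXtViX)))
  logdet_XtX <- 2 * sum(log(diag(chol(crossprod(X)))))
  -0.5 * ((n - p) * log(2 * pi) + logdet_V + logdet_XtViX - logdet_XtX + ytPy)
}

# Profiled REML pieces for V = sigma2_e * (ga G + gd D + I). Returns the
# profiled log-likelihood together with the profiled sigma2_e and GLS beta.
profiled_reml <- function(lg, y, X, G, D, logdet_XtX) {
  n <- length(y)
  p <- ncol(X)
  lg <- pmin(pmax(lg, -30), 30)
  g <- exp(lg)
  W <- g[1L] * G + diag(1, n)
  if (!is.null(D)) W <- W + g[2L] * D
  cW <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(cW)) return(list(loglik = -Inf))
  Z <- backsolve(cW, cbind(y, X), transpose = TRUE)
  zy <- Z[, 1L]
  ZX <- Z[, -1L, drop = FALSE]
  XtWiX <- crossprod(ZX)
  cXtWiX <- tryCatch(chol(XtWiX), error = function(e) NULL)
  if (is.null(cXtWiX)) return(list(loglik = -Inf))
  Xty <- crossprod(ZX, zy)
  beta <- backsolve(cXtWiX, backsolve(cXtWiX, Xty, transpose = TRUE))
  ssr <- sum(zy^2) - drop(crossprod(Xty, beta))
  if (ssr <= 0) return(list(loglik = -Inf))
  s2e <- ssr / (n - p)
  loglik <- -0.5 * ((n - p) * (log(2 * pi * s2e) + 1) +
                      2 * sum(log(diag(cW))) + 2 * sum(log(diag(cXtWiX))) -
                      logdet_XtX)
  list(loglik = loglik, s2e = s2e, beta = drop(beta), gamma = g)
}

#' REML estimation of additive and dominance variance components
#'
#' Fits `y = X beta + a + d + e` with `Cov(a) = G sigma2_a`,
#' `Cov(d) = D sigma2_d`, `Cov(e) = I sigma2_e` by restricted maximum
#' likelihood. The residual variance is profiled out and the log variance
#' ratios are maximized by Nelder-Mead from three starting points (equal
#' split, additive-heavy, dominance-heavy); the best local optimum is
#' returned. Estimates below `1e-6 * var(y)` are reported as 0.
#'
#' @param pheno data frame with an id column, optional fixed-effect factor
#'   columns and the trait column.
#' @param G additive relationship matrix with individual ids as row names.
#' @param D optional dominance relationship matrix (same ids); `NULL` fits
#'   the additive-only model.
#' @param fixed one-sided formula for the fixed effects (an intercept is
#'   always included), e.g. `~ trial`. Default `~ 1` (mean only).
#' @param trait name of the trait column; default `"y"`.
#' @param id name of the id column; default `"id"`.
#' @param max_iter Nelder-Mead evaluation budget per start; default 200.
#' @param tol relative log-likelihood convergence tolerance; default 1e-8.
#' @param se if `TRUE`, approximate standard errors from the numerical
#'   Hessian of the (unprofiled) REML log-likelihood.
#' @return object of class `varcomp_fit`: `sigma2_a`, `sigma2_d`,
#'   `sigma2_e`, `h2`, `d2`, `loglik`, `beta`, `converged`, `n_iter`, `n`,
#'   and `se` (named vector, when requested).
#' @export
reml_fit <- function(pheno, G, D = NULL, fixed = ~1, trait = "y", id = "id",
                     max_iter = 200L, tol = 1e-8, se = FALSE) {
  ids <- rownames(G)
  if (is.null(ids)) stop("G must carry individual ids as row names")
  if (!all(c(id, trait) %in% colnames(pheno))) {
    stop("phenotype table must contain columns '", id, "' and '", trait, "'")
  }
  idx <- match(ids, as.character(pheno[[id]]))
  if (anyNA(idx)) {
    stop("phenotypes missing for ", sum(is.na(idx)),
         " individual(s) present in G")
  }
  pheno <- pheno[idx, , drop = FALSE]
  y <- as.numeric(pheno[[trait]])
  X <- stats::model.matrix(fixed, data = pheno)
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effects design matrix is rank deficient")
  if (n < p + 3L) stop("too few individuals for the fixed-effects design")
  Gm <- unclass(G)[, , drop = FALSE]
  Dm <- if (!is.null(D)) unclass(D)[, , drop = FALSE] else NULL
  nonidentifiable <- FALSE
  if (!is.null(Dm) && max(abs(Gm - Dm)) < 1e-10) {
    warning("G and D are (numerically) identical: additive and dominance ",
            "variances are not separately identifiable")
    nonidentifiable <- TRUE
  }
  logdet_XtX <- 2 * sum(log(diag(chol(crossprod(X)))))
  obj <- function(lg) -profiled_reml(lg, y, X, Gm, Dm, logdet_XtX)$loglik

  vy <- stats::var(y)
  n_iter <- 0L
  if (is.null(Dm)) {
    starts <- list(log(1), log(8), log(1 / 8))
    best <- NULL
    for (s0 in starts) {
      opt <- stats::optim(s0, obj, method = "Brent", lower = -30, upper = 30,
                          control = list(maxit = max_iter))
      n_iter <- n_iter + opt$counts[[1L]]
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  } else {
    starts <- list(c(0, 0), c(log(8), log(0.5)), c(log(0.5), log(8)))
    best <- NULL
    for (s0 in starts) {
      opt <- stats::optim(s0, obj, method = "Nelder-Mead",
                          control = list(maxit = max_iter, reltol = tol))
      n_iter <- n_iter + opt$counts[[1L]]
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  }
  fit <- profiled_reml(best$par, y, X, Gm, Dm, logdet_XtX)
  s2e <- fit$s2e
  s2a <- fit$gamma[1L] * s2e
  s2d <- if (is.null(Dm)) NA_real_ else fit$gamma[2L] * s2e
  # boundary reporting: tiny components are genuinely zero
  floor_to_zero <- function(v) if (!is.na(v) && v < 1e-6 * vy) 0 else v
  s2a <- floor_to_zero(s2a)
  s2d <- if (is.null(Dm)) NA_real_ else floor_to_zero(s2d)
  ratios <- variance_ratios(c(s2a, if (is.null(Dm)) 0 else s2d, s2e))
  out <- structure(list(
    sigma2_a = s2a, sigma2_d = s2d, sigma2_e = s2e,
    h2 = ratios$h2, d2 = if (is.null(Dm)) NA_real_ else ratios$d2,
    loglik = fit$loglik, beta = fit$beta,
    converged = (best$convergence == 0L) && !nonidentifiable,
    n_iter = n_iter, n = n), class = "varcomp_fit")
  if (se) {
    sig <- if (is.null(Dm)) c(s2a, s2e) else c(s2a, s2d, s2e)
    H <- tryCatch(num_hessian(function(v) -reml_loglik(v, y, X, Gm, Dm), sig),
                  error = function(e) NULL)
    out$se <- tryCatch({
      v <- sqrt(diag(solve(H)))
      names(v) <- if (is.null(Dm)) c("sigma2_a", "sigma2_e") else
        c("sigma2_a", "sigma2_d", "sigma2_e")
      v
    }, error = function(e) NULL)
  }
  out
}

num_hessian <- function(fn, x, h = NULL) {
  k <- length(x)
  h <- h %||% pmax(abs(x), 1e-4) * 1e-4
  H <- matrix(0, k, k)
  f0 <- fn(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- rep(0, k)
      ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) +
             fn(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Variance ratios (heritability and dominance proportion)
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_d + sigma2_e)` and analogously `d2`;
#' the denominator is the phenotypic variance implied by the fit.
#'
#' @param fit a `varcomp_fit`, or a numeric vector
#'   `c(sigma2_a, sigma2_d, sigma2_e)`.
#' @return list with `h2`, `d2` and `phenotypic_variance` (`NA` ratios when
#'   all components are zero).
#' @export
variance_ratios <- function(fit) {
  v <- if (inherits(fit, "varcomp_fit")) {
    c(fit$sigma2_a, if (is.na(fit$sigma2_d)) 0 else fit$sigma2_d,
      fit$sigma2_e)
  } else as.numeric(fit)
  stopifnot(length(v) == 3L)
  total <- sum(v)
  if (total <= 0) {
    return(list(h2 = NA_real_, d2 = NA_real_, phenotypic_variance = total))
  }
  list(h2 = v[1L] / total, d2 = v[2L] / total, phenotypic_variance = total)
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat("REML variance components (n =", x$n, ")\n")
  cat(sprintf("  sigma2_a = %.4f  sigma2_d = %s  sigma2_e = %.4f\n",
              x$sigma2_a,
              if (is.na(x$sigma2_d)) "-" else sprintf("%.4f", x$sigma2_d),
              x$sigma2_e))
  cat(sprintf("  h2 = %.4f  d2 = %s  logLik = %.3f  converged: %s\n",
              x$h2, if (is.na(x$d2)) "-" else sprintf("%.4f", x$d2),
              x$loglik, x$converged))
  invisible(x)
}
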