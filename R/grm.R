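#' Assemble a genomic relationship matrix from scale matrices
#'
#' `G = H_a H_a' / SC_a` (additive) or `D = H_d H_d' / SC_d` (dominance).
#' For methods scaled by the realized trace (NOIA, GSP-N) the average
#' diagonal of the result is exactly 1 up to floating-point rounding.
#'
#' @param s a `scale_matrices` object ([build_scale_matrices()]).
#' @param kind `"additive"` or `"dominance"`.
#' @return an n x n symmetric matrix of class `relationship_matrix` with
#'   attributes `kind`, `method` and `denominator_mode`.
#' @export
build_grm <- function(s, kind = c("additive", "dominance")) {
  kind <- match.arg(kind)
  H <- if (kind == "additive") s$Ha else s$Hd
  SC <- if (kind == "additive") s$SC_a else s$SC_d
  if (!is.finite(SC) || SC <= 1e-12) {
    stop("scaling denominator for the ", kind,
         " relationship matrix is zero (no informative markers)")
  }
  R <- tcrossprod(H) / SC
  structure(R, class = c("relationship_matrix", class(R)),
            kind = kind, method = s$method,
            denominator_mode = s$denominator_mode)
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix [%s, %s]: %d x %d\n",
              attr(x, "method") %||% "?", attr(x, "kind") %||% "?",
              nrow(x), ncol(x)))
  s <- matrix_summary(x)
  cat(sprintf(" avg diagonal %.3f, avg off-diagonal %.3f, eigenvalues [%.3f, %.3f]\n",
              s$avg_diagonal, s$avg_off_diagonal,
              s$min_eigenvalue, s$max_eigenvalue))
  invisible(x)
}

#' Summary statistics of a relationship matrix
#'
#' Average diagonal, average off-diagonal `(sum - trace)/(n^2 - n)`, and the
#' eigenvalue range from a symmetric eigensolver on the exact (unridged)
#' matrix. Tiny negative eigenvalues above `-1e-8` (rounding noise on a
#' Gram matrix) are clamped to 0.
#'
#' @param r a square symmetric matrix (usually a `relationship_matrix`).
#' @return list with `avg_diagonal`, `avg_off_diagonal`, `min_eigenvalue`,
#'   `max_eigenvalue`.
#' @export
matrix_summary <- function(r) {
  n <- nrow(r)
  stopifnot(n >= 2L, n == ncol(r))
  ev <- eigen(unclass(r), symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0 & ev > -1e-8] <- 0
  list(avg_diagonal = mean(diag(r)),
       avg_off_diagonal = (sum(r) - sum(diag(r))) / (n^2 - n),
       min_eigenvalue = min(ev),
       max_eigenvalue = max(ev))
}

#' Kullback-Leibler divergence between two relationship matrices
#'
#' Treats P and Q as covariance matrices of n-dimensional Gaussians and
#' computes `D_KL(P || Q) = 0.5 [ tr(Q^-1 P) + (mu_Q - mu_P)' Q^-1
#' (mu_Q - mu_P) - n + ln(|Q|/|P|) ]` in nats. Genetic effects in GBLUP have
#' zero mean, so both mean vectors default to zero and the quadratic term
#' vanishes. Relationship matrices built from fewer markers than individuals
#' are singular, so a small ridge is added to both diagonals before
#' factorization.
#'
#' @param P,Q square symmetric matrices of the same dimension (same
#'   individual ordering).
#' @param ridge regularization added to both diagonals; default `1e-6`.
#' @param mu_p,mu_q optional mean vectors; default zero.
#' @return list of class `kl_divergence`: `value` (nats), `direction`,
#'   `ridge_used`.
#' @export
kl_divergence <- function(P, Q, ridge = 1e-6, mu_p = NULL, mu_q = NULL) {
  n <- nrow(P)
  stopifnot(n == ncol(P), identical(dim(P), dim(Q)))
  Pr <- unclass(P) + diag(ridge, n)
  Qr <- unclass(Q) + diag(ridge, n)
  chol_or_fail <- function(M, name) {
    tryCatch(chol(M), error = function(e) {
      stop(name, " is not positive definite after ridging; ",
           "try a larger 'ridge'", call. = FALSE)
    })
  }
  cP <- chol_or_fail(Pr, "P")
  cQ <- chol_or_fail(Qr, "Q")
  logdet_P <- 2 * sum(log(diag(cP)))
  logdet_Q <- 2 * sum(log(diag(cQ)))
  Qinv <- chol2inv(cQ)
  tr_term <- sum(Qinv * Pr)
  quad <- 0
  if (!is.null(mu_p) || !is.null(mu_q)) {
    dmu <- (mu_q %||% rep(0, n)) - (mu_p %||% rep(0, n))
    quad <- drop(crossprod(dmu, Qinv %*% dmu))
  }
  value <- 0.5 * (tr_term + quad - n + logdet_Q - logdet_P)
  structure(list(value = value,
                 direction = c(attr(P, "method") %||% "P",
                               attr(Q, "method") %||% "Q"),
                 ridge_used = ridge),
            class = "kl_divergence")
}

#' @export
print.kl_divergence <- function(x, ...) {
  cat(sprintf("KL(%s || %s) = %.4f nats (ridge %g)\n",
              x$direction[1L], x$direction[2L], x$value, x$ridge_used))
  invisible(x)
}

#' Write / read a relationship matrix as TSV
#'
#' Square tab-separated layout: first column and header row carry the
#' individual ids; values at full double precision.
#'
#' @param r matrix with individual ids as dimnames.
#' @param path file path.
#' @export
write_grm <- function(r, path) {
  df <- data.frame(id = rownames(r) %||% paste0("ind_", seq_len(nrow(r))),
                   as.data.frame(unclass(r)), check.names = FALSE)
  write_tsv_atomic(df, path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  ids <- as.character(dt[[1L]])
  R <- as.matrix(dt[, -1L, drop = FALSE])
  dimnames(R) <- list(ids, colnames(dt)[-1L])
  if (!identical(rownames(R), colnames(R))) {
    stop("relationship matrix file is not square with matching ids: ", path)
  }
  R
}
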