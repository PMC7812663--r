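# Per-marker additive and dominance scale triples ----------------------------
#
# A "scale" is the per-genotype coefficient (one value each for AA, Aa, aa)
# used to center a marker's column in the additive or dominance incidence
# matrix, analogous to a contrast in ANOVA. Six parameterizations are
# supported; they differ in what they assume about genotype frequencies and
# in whether additive and dominance scales are forced to be orthogonal.

DEGENERACY_TOL <- 1e-12

#' @rdname marker_scales
#' @export
scale_methods <- function() c("HW", "NO-HW", "NOIA", "GSP-A", "GSP-D", "GSP-N")

new_marker_scales <- function(f, method, u, v, sc_a, sc_d, a_ok, d_ok,
                              n = NULL) {
  out <- data.frame(
    marker = f$marker %||% paste0("mk_", seq_len(nrow(u))),
    u_AA = u[, 1L], u_Aa = u[, 2L], u_aa = u[, 3L],
    v_AA = v[, 1L], v_Aa = v[, 2L], v_aa = v[, 3L],
    sc_a_contrib = sc_a, sc_d_contrib = sc_d,
    a_ok = a_ok, d_ok = d_ok,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "n") <- n
  class(out) <- c("marker_scales", "data.frame")
  out
}

#' Classical Hardy-Weinberg (VanRaden / Su-Vitezica) scales
#'
#' Additive triple `(2 - 2p, 1 - 2p, -2p)` for genotypes AA/Aa/aa and
#' dominance triple `(-2pq, 1 - 2pq, -2pq)`, with per-marker scaling
#' contributions `2pq` (additive) and `2pq(1 - 2pq)` (dominance). Centering
#' relies on HWE genotype proportions; on non-HWE panels the dominance column
#' mean is `pAa - 2pq`, not zero.
#'
#' @param f per-marker genotype frequencies ([compute_frequencies()] output,
#'   or any data frame with columns `pAA`, `pAa`, `paa`, `p`, `q`).
#' @return a `marker_scales` data frame: additive triple (`u_AA`, `u_Aa`,
#'   `u_aa`), dominance triple (`v_AA`, `v_Aa`, `v_aa`), scaling
#'   contributions `sc_a_contrib`/`sc_d_contrib`, and flags `a_ok`/`d_ok`
#'   marking markers whose additive/dominance scale is non-degenerate.
#' @export
hw_scales <- function(f) {
  p <- f$p; q <- f$q
  two_pq <- 2 * p * q
  u <- cbind(2 - 2 * p, 1 - 2 * p, -2 * p)
  v <- cbind(-two_pq, 1 - two_pq, -two_pq)
  new_marker_scales(f, "HW", u, v,
                    sc_a = two_pq, sc_d = two_pq * (1 - two_pq),
                    a_ok = two_pq > DEGENERACY_TOL,
                    d_ok = two_pq * (1 - two_pq) > DEGENERACY_TOL)
}

#' Non-HWE (biological, Alvarez-Castro) scales
#'
#' Centering with the observed genotype frequencies: additive triple
#' `(1 - (pAA - paa), -(pAA - paa), -1 - (pAA - paa))` and dominance triple
#' `(-pAa, 1 - pAa, -pAa)`. Per-marker scaling contributions are the
#' genotypic variances `pAA + paa - (pAA - paa)^2` and `pAa - pAa^2`.
#' The additive triple reduces to the VanRaden scales because
#' `p = pAA + pAa/2`. Additive and dominance scales are not orthogonal
#' unless `pAA = paa` or `pAa = 0`.
#'
#' @inheritParams hw_scales
#' @return a `marker_scales` data frame (see [hw_scales()]).
#' @export
nohw_scales <- function(f) {
  d <- f$pAA - f$paa
  wA <- f$pAA + f$paa - d^2
  u <- cbind(1 - d, -d, -1 - d)
  v <- cbind(-f$pAa, 1 - f$pAa, -f$pAa)
  wD <- f$pAa - f$pAa^2
  new_marker_scales(f, "NO-HW", u, v, sc_a = wA, sc_d = wD,
                    a_ok = wA > DEGENERACY_TOL, d_ok = wD > DEGENERACY_TOL)
}


#' NOIA orthogonal scales
#'
#' Natural and orthogonal interactions approach: the additive triple is
#' identical to the non-HWE triple ([nohw_scales()]); the dominance triple is
#' `(-2 pAa paa, 4 pAA paa, -2 pAA pAa) / (pAA + paa - (pAA - paa)^2)`.
#' The triples satisfy the three orthogonality conditions (zero
#' frequency-weighted mean of each scale and zero frequency-weighted
#' cross-product) for any genotype frequencies. When the relationship
#' matrices are assembled, NOIA divides by the realized trace
#' `tr(H H')/n` rather than the expected variance sum.
#'
#' Markers whose dominance denominator `pAA + paa - (pAA - paa)^2` falls
#' below tolerance (monomorphic, or heterozygotes only) are flagged
#' degenerate.
#'
#' @inheritParams hw_scales
#' @return a `marker_scales` data frame (see [hw_scales()]).
#' @export
noia_scales <- function(f) {
  d <- f$pAA - f$paa
  wA <- f$pAA + f$paa - d^2
  a_ok <- wA > DEGENERACY_TOL
  u <- cbind(1 - d, -d, -1 - d)
  denom <- ifelse(a_ok, wA, NA_real_)
  v <- cbind(-2 * f$pAa * f$paa, 4 * f$pAA * f$paa, -2 * f$pAA * f$pAa) / denom
  wD <- 4 * f$pAA * f$pAa * f$paa / denom
  new_marker_scales(f, "NOIA", u, v, sc_a = wA, sc_d = wD,
                    a_ok = a_ok, d_ok = a_ok & !is.na(wD) & wD > DEGENERACY_TOL)
}

#' Gram-Schmidt scales starting from the additive vector (GSP-A)
#'
#' The additive vector is kept as the non-HWE additive scale and the
#' dominance vector is orthogonalized against it. The resulting dominance
#' triple is algebraically identical to the NOIA triple; the only difference
#' from NOIA is that the relationship matrices are scaled by the *expected*
#' trace per individual: `sum_j [pAA + paa - (pAA - paa)^2]` for G and
#' `sum_j [4 pAA pAa paa / (pAA + paa - (pAA - paa)^2)]` for D.
#'
#' @inheritParams hw_scales
#' @return a `marker_scales` data frame (see [hw_scales()]).
#' @export
gspa_scales <- function(f) {
  base <- nohw_scales(f)
  u <- as.matrix(base[, c("u_AA", "u_Aa", "u_aa")])   # tau_A = u (kept)
  v0 <- as.matrix(base[, c("v_AA", "v_Aa", "v_aa")])
  wA <- base$sc_a_contrib                             # <tau_A, tau_A>/n
  a_ok <- base$a_ok
  # projection coefficient <tau_A, v>/<tau_A, tau_A> = (-pAa)(pAA-paa)/wA
  coef <- ifelse(a_ok, (-f$pAa) * (f$pAA - f$paa) / wA, NA_real_)
  v <- v0 - coef * u                                  # tau_D = v - proj
  wD <- 4 * f$pAA * f$pAa * f$paa / ifelse(a_ok, wA, NA_real_)
  new_marker_scales(f, "GSP-A", u, v, sc_a = wA, sc_d = wD,
                    a_ok = a_ok, d_ok = a_ok & !is.na(wD) & wD > DEGENERACY_TOL)
}

#' Gram-Schmidt scales starting from the dominance vector (GSP-D)
#'
#' The dominance vector is kept as the non-HWE dominance scale
#' `(-pAa, 1 - pAa, -pAa)` (scaling contribution `pAa - pAa^2`) and the
#' additive vector is orthogonalized against it, giving
#' `(2 paa / (1 - pAa), 0, -2 pAA / (1 - pAa))` with scaling contribution
#' `4 pAA paa / (pAA + paa)`. The heterozygote additive scale is exactly
#' zero. Markers with `pAa = 1` have no additive scale and are flagged.
#'
#' @inheritParams hw_scales
#' @return a `marker_scales` data frame (see [hw_scales()]).
#' @export
gspd_scales <- function(f) {
  pAA <- f$pAA; pAa <- f$pAa; paa <- f$paa
  hom <- pAA + paa                       # = 1 - pAa
  a_def <- hom > DEGENERACY_TOL          # pAa < 1
  denom <- ifelse(a_def, hom, NA_real_)
  u <- cbind(2 * paa / denom, 0, -2 * pAA / denom)
  sc_a <- 4 * pAA * paa / denom
  v <- cbind(-pAa, 1 - pAa, -pAa)
  sc_d <- pAa - pAa^2
  new_marker_scales(f, "GSP-D", u, v, sc_a = sc_a, sc_d = sc_d,
                    a_ok = a_def & !is.na(sc_a) & sc_a > DEGENERACY_TOL,
                    d_ok = sc_d > DEGENERACY_TOL)
}

#' Orthonormal Gram-Schmidt scales (GSP-N)
#'
#' The GSP-A triples divided by the norms of the n-dimensional scale
#' vectors, `||tau_A|| = sqrt(n (pAA + paa - (pAA - paa)^2))` and
#' `||tau_D|| = sqrt(n 4 pAA pAa paa / (pAA + paa - (pAA - paa)^2))`, so
#' every marker's scale vector has unit length and all markers contribute
#' equally to the relationship matrices. The matrices are then scaled by the
#' realized trace `tr(H H')/n`.
#'
#' @inheritParams hw_scales
#' @param n number of individuals (the norms grow with `sqrt(n)`).
#' @return a `marker_scales` data frame (see [hw_scales()]).
#' @export
gspn_scales <- function(f, n) {
  stopifnot(length(n) == 1L, n >= 1)
  base <- gspa_scales(f)
  norm_a <- sqrt(n * base$sc_a_contrib)
  norm_d <- sqrt(n * base$sc_d_contrib)
  u <- as.matrix(base[, c("u_AA", "u_Aa", "u_aa")]) /
    ifelse(base$a_ok, norm_a, NA_real_)
  v <- as.matrix(base[, c("v_AA", "v_Aa", "v_aa")]) /
    ifelse(base$d_ok, norm_d, NA_real_)
  # each retained column contributes 1/n to tr(H H')/n in expectation
  new_marker_scales(f, "GSP-N", u, v,
                    sc_a = ifelse(base$a_ok, 1 / n, 0),
                    sc_d = ifelse(base$d_ok, 1 / n, 0),
                    a_ok = base$a_ok, d_ok = base$d_ok, n = n)
}

#' Per-marker scale triples for a named parameterization
#'
#' Dispatcher over [hw_scales()], [nohw_scales()], [noia_scales()],
#' [gspa_scales()], [gspd_scales()] and [gspn_scales()].
#'
#' @inheritParams hw_scales
#' @param method one of `scale_methods()`; case-insensitive, `"nohw"`,
#'   `"gspa"` etc. also accepted.
#' @param n number of individuals (required for `GSP-N`).
#' @return a `marker_scales` data frame (see [hw_scales()]).
#' @export
marker_scales <- function(f, method, n = NULL) {
  method <- normalize_method(method)
  switch(method,
         "HW" = hw_scales(f),
         "NO-HW" = nohw_scales(f),
         "NOIA" = noia_scales(f),
         "GSP-A" = gspa_scales(f),
         "GSP-D" = gspd_scales(f),
         "GSP-N" = {
           if (is.null(n)) stop("GSP-N scales require the individual count 'n'")
           gspn_scales(f, n)
         })
}

normalize_method <- function(method) {
  key <- gsub("[^a-z]", "", tolower(method))
  methods <- scale_methods()
  names(methods) <- gsub("[^a-z]", "", tolower(methods))
  if (!key %in% names(methods)) {
    usage_error("unknown method '", method, "'; valid methods: ",
                paste(tolower(gsub("-", "", scale_methods())), collapse = ", "))
  }
  methods[[key]]
}

# Denominator convention per method: NOIA and GSP-N divide by the realized
# trace of H H' per individual; the others by the expected variance sums.
denominator_mode_for <- function(method) {
  if (method %in% c("NOIA", "GSP-N")) "realized_trace" else "expected_sum"
}

#' Build centered scale matrices H_a and H_d for a genotype panel
#'
#' Fills the n x m additive and dominance scale matrices from the per-marker
#' triples (individual i's entry in column j is the triple value matching its
#' genotype), with missing genotypes set to 0 (mean imputation after
#' centering, which keeps column sums at zero on the observed data).
#' Degenerate markers (flagged `a_ok`/`d_ok` FALSE) get all-zero columns and
#' are excluded from the scaling denominators.
#'
#' @param g a [genotype_matrix].
#' @param method one of `scale_methods()`.
#' @param f optional precomputed `genotype_freqs`; defaults to
#'   `compute_frequencies(g)`.
#' @param denominator override of the per-method denominator convention:
#'   `"expected_sum"` (sum of per-marker variance contributions) or
#'   `"realized_trace"` (`tr(H H')/n`). Default `NULL` uses the method's own
#'   convention (realized trace for NOIA and GSP-N, expected sums otherwise).
#' @return an object of class `scale_matrices`: list with `method`, `Ha`,
#'   `Hd`, `SC_a`, `SC_d`, `denominator_mode`, `excluded_additive`,
#'   `excluded_dominance`, `n`, `m`.
#' @export
build_scale_matrices <- function(g, method, f = compute_frequencies(g),
                                 denominator = NULL) {
  method <- normalize_method(method)
  n <- nrow(g)
  s <- marker_scales(f, method, n = n)
  if (!any(s$a_ok) && !any(s$d_ok)) {
    stop("all markers are degenerate for method ", method)
  }
  codes <- unclass(g)
  fill <- function(tri, ok) {
    # tri: m x 3 (AA, Aa, aa); map codes 2/1/0 -> columns 1/2/3
    H <- matrix(0, nrow(codes), ncol(codes), dimnames = dimnames(codes))
    for (code in 0:2) {
      col <- 3L - code
      idx <- which(!is.na(codes) & codes == code, arr.ind = TRUE)
      if (nrow(idx)) H[idx] <- tri[idx[, 2L], col]
    }
    H[, !ok] <- 0
    H
  }
  Ha <- fill(as.matrix(s[, c("u_AA", "u_Aa", "u_aa")]), s$a_ok)
  Hd <- fill(as.matrix(s[, c("v_AA", "v_Aa", "v_aa")]), s$d_ok)
  mode <- denominator %||% denominator_mode_for(method)
  mode <- match.arg(mode, c("expected_sum", "realized_trace"))
  SC_a <- if (mode == "realized_trace") sum(Ha^2) / n else
    sum(s$sc_a_contrib[s$a_ok])
  SC_d <- if (mode == "realized_trace") sum(Hd^2) / n else
    sum(s$sc_d_contrib[s$d_ok])
  structure(list(method = method, Ha = Ha, Hd = Hd,
                 SC_a = SC_a, SC_d = SC_d, denominator_mode = mode,
                 excluded_additive = s$marker[!s$a_ok],
                 excluded_dominance = s$marker[!s$d_ok],
                 n = n, m = ncol(codes)),
            class = "scale_matrices")
}

#' @export
print.scale_matrices <- function(x, ...) {
  cat(sprintf("scale_matrices [%s]: n=%d, m=%d, SC_a=%.4f, SC_d=%.4f (%s)\n",
              x$method, x$n, x$m, x$SC_a, x$SC_d, x$denominator_mode))
  if (length(x$excluded_additive))
    cat(" excluded from H_a:", length(x$excluded_additive), "marker(s)\n")
  if (length(x$excluded_dominance))
    cat(" excluded from H_d:", length(x$excluded_dominance), "marker(s)\n")
  invisible(x)
}

#' Angle between the additive and dominance scale vectors of each marker
#'
#' Under the non-HWE parameterization the n-dimensional additive and
#' dominance scale vectors of marker j have expected inner product
#' `n (-pAa)(pAA - paa)` and norms
#' `sqrt(n [pAA + paa - (pAA - paa)^2])` and `sqrt(n pAa (1 - pAa))`.
#' `cos(theta)` is their ratio (the individual count cancels); `theta = 90`
#' degrees means the scales are orthogonal, which happens exactly when the
#' two homozygote frequencies are equal or there are no heterozygotes.
#'
#' @inheritParams hw_scales
#' @param n number of individuals (any positive value; it cancels in the
#'   angle but is reported in the inner product and norms).
#' @return data frame with columns `marker`, `inner_product`, `norm_u`,
#'   `norm_v`, `cos_theta` and `theta_degrees` (`NA` where a norm vanishes).
#' @export
marker_angle <- function(f, n = 1) {
  d <- f$pAA - f$paa
  wA <- f$pAA + f$paa - d^2
  wD <- f$pAa * (1 - f$pAa)
  inner <- n * (-f$pAa) * d
  norm_u <- sqrt(n * wA)
  norm_v <- sqrt(n * wD)
  defined <- wA > DEGENERACY_TOL & wD > DEGENERACY_TOL
  cos_theta <- ifelse(defined,
                      pmin(1, pmax(-1, inner / (norm_u * norm_v))), NA_real_)
  data.frame(marker = f$marker %||% paste0("mk_", seq_along(inner)),
             inner_product = inner, norm_u = norm_u, norm_v = norm_v,
             cos_theta = cos_theta,
             theta_degrees = acos(cos_theta) * 180 / pi,
             stringsAsFactors = FALSE)
}

#' Verify the orthogonality conditions of a set of scale triples
#'
#' Computes the three frequency-weighted sums per marker: the mean of the
#' additive scale, the mean of the dominance scale, and the
#' additive-dominance cross-product. A parameterization yields an orthogonal
#' partition of variance when all three vanish; the cross-product residual is
#' the per-individual expected inner product of the two scale vectors.
#'
#' @param s a `marker_scales` data frame (any of the `*_scales()` outputs).
#' @param f the genotype frequencies the triples were computed from.
#' @param tol certification tolerance on the cross-product residual.
#' @return data frame with per-marker residuals `mean_additive`,
#'   `mean_dominance`, `cross_product`; attribute `"orthogonal"` is `TRUE`
#'   when the largest defined cross-product residual is below `tol`.
#' @export
verify_orthogonality <- function(s, f, tol = 1e-10) {
  w <- cbind(f$pAA, f$pAa, f$paa)
  u <- as.matrix(s[, c("u_AA", "u_Aa", "u_aa")])
  v <- as.matrix(s[, c("v_AA", "v_Aa", "v_aa")])
  out <- data.frame(marker = s$marker,
                    mean_additive = rowSums(w * u),
                    mean_dominance = rowSums(w * v),
                    cross_product = rowSums(w * u * v),
                    stringsAsFactors = FALSE)
  defined <- s$a_ok & s$d_ok
  attr(out, "orthogonal") <-
    all(abs(out$cross_product[defined]) < tol, na.rm = TRUE)
  out
}
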