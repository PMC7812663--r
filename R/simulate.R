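# Genotype and phenotype simulation -----------------------------------------
#
# The generator emulates the structure of a crossbred (F1) SNP panel: either
# a single-parameter inbreeding coefficient F (negative F = heterozygote
# excess, as in F1 crosses; per-marker genotype probabilities
# p^2 + Fpq, 2pq(1-F), q^2 + Fpq) or an explicit F1 cross between two
# parental pools with their own allele-frequency laws (genotype
# probabilities p1 p2, p1 q2 + p2 q1, q1 q2).
#
# Sub-seeds for the logical random streams (frequencies, genotypes, effects,
# noise) are derived deterministically from the user seed so that, e.g.,
# genotypes stay identical when only trait parameters change.

derive_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, k)
}

draw_freqs <- function(m, law) {
  if (length(law) == 1L) rep(law, m)
  else stats::runif(m, law[1L], law[2L])
}

#' Simulate a genotype panel with controllable Hardy-Weinberg departure
#'
#' Two modes:
#' \describe{
#'   \item{`"f1"`}{each marker is an F1 cross between two parental pools
#'     with allele frequencies drawn from `freq` and `freq2`; heterozygote
#'     frequency is `p1 q2 + p2 q1`, which exceeds the HWE expectation
#'     whenever the pools differ (crossbred signature).}
#'   \item{`"inbreeding"`}{genotypes drawn from
#'     `(p^2 + Fpq, 2pq(1 - F), q^2 + Fpq)`; negative `F` gives a
#'     heterozygote excess of `-F` in expectation. Markers for which the
#'     drawn allele frequency makes `F` infeasible (a probability outside
#'     `[0, 1]`) are redrawn; the count is recorded in the `"redrawn"`
#'     attribute. Optional per-marker jitter on `F` reflects that real
#'     disequilibrium is locus-heterogeneous.}
#' }
#' Defaults reproduce the conditions the package is characterized under:
#' a 903-individual crossbred panel and, in inbreeding mode, a genome-wide
#' average heterozygote excess of 4.7% (`F = -0.047`).
#'
#' @param n number of individuals (default 903).
#' @param m number of markers (default 2000).
#' @param mode `"f1"` or `"inbreeding"`.
#' @param freq allele-frequency law for the (first parental) pool: a range
#'   `c(lo, hi)` for uniform draws or a single fixed value. Default
#'   `c(0.05, 0.95)`.
#' @param freq2 law for the second parental pool (`"f1"` mode); defaults to
#'   `freq`.
#' @param F inbreeding coefficient (`"inbreeding"` mode); default `-0.047`.
#' @param F_jitter standard deviation of per-marker Gaussian jitter on `F`;
#'   default 0.
#' @param missing_rate proportion of genotypes set missing; default 0.
#' @param seed integer seed; same seed gives byte-identical output.
#' @return a [genotype_matrix]; attribute `"freqs"` holds the simulated
#'   per-marker genotype probabilities, `"redrawn"` the number of redrawn
#'   markers.
#' @export
simulate_genotypes <- function(n = 903, m = 2000,
                               mode = c("f1", "inbreeding"),
                               freq = c(0.05, 0.95), freq2 = freq,
                               F = -0.047, F_jitter = 0,
                               missing_rate = 0, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(missing_rate >= 0, missing_rate < 1)
  seeds <- derive_seeds(seed, 2L)

  set.seed(seeds[1L])  # frequency stream
  redrawn <- 0L
  if (mode == "f1") {
    p1 <- draw_freqs(m, freq)
    p2 <- draw_freqs(m, freq2)
    probs <- cbind(AA = p1 * p2,
                   Aa = p1 * (1 - p2) + p2 * (1 - p1),
                   aa = (1 - p1) * (1 - p2))
  } else {
    p <- draw_freqs(m, freq)
    Fj <- F + if (F_jitter > 0) stats::rnorm(m, 0, F_jitter) else 0
    probs <- cbind(AA = p^2 + Fj * p * (1 - p),
                   Aa = 2 * p * (1 - p) * (1 - Fj),
                   aa = (1 - p)^2 + Fj * p * (1 - p))
    bad <- which(probs[, "AA"] < 0 | probs[, "Aa"] < 0 | probs[, "aa"] < 0)
    while (length(bad)) {
      redrawn <- redrawn + length(bad)
      p[bad] <- draw_freqs(length(bad), freq)
      Fj2 <- F + if (F_jitter > 0) stats::rnorm(length(bad), 0, F_jitter) else 0
      if (length(Fj) > 1L) Fj[bad] <- Fj2 else Fj <- Fj2
      pb <- p[bad]; fb <- if (length(Fj) > 1L) Fj[bad] else Fj
      probs[bad, ] <- cbind(pb^2 + fb * pb * (1 - pb),
                            2 * pb * (1 - pb) * (1 - fb),
                            (1 - pb)^2 + fb * pb * (1 - pb))
      bad <- which(probs[, "AA"] < 0 | probs[, "Aa"] < 0 | probs[, "aa"] < 0)
    }
  }

  set.seed(seeds[2L])  # genotype stream
  u <- matrix(stats::runif(n * m), n, m)
  thr_AA <- matrix(probs[, "AA"], n, m, byrow = TRUE)
  thr_Aa <- matrix(probs[, "AA"] + probs[, "Aa"], n, m, byrow = TRUE)
  codes <- matrix(0L, n, m)
  codes[u < thr_Aa] <- 1L
  codes[u < thr_AA] <- 2L
  if (missing_rate > 0) {
    codes[matrix(stats::runif(n * m) < missing_rate, n, m)] <- NA_integer_
  }
  g <- genotype_matrix(codes,
                       ids = sprintf("ind_%04d", seq_len(n)),
                       markers = sprintf("mk_%05d", seq_len(m)))
  attr(g, "freqs") <- probs
  attr(g, "redrawn") <- redrawn
  g
}

#' Simulate phenotypes under the additive-dominance marker model
#'
#' Phenotypes follow
#' `y_i = mu + trial_i + sum_j z_ij a_j + sum_j s_ij d_j + e_i`, with
#' `z in {1, 0, -1}` and `s in {0, 1, 0}` for genotypes AA/Aa/aa (genotype
#' codes 2/1/0; missing genotypes contribute 0). Marker effects are drawn
#' i.i.d. normal and then rescaled so that the realized sample variances of
#' the additive and dominance genetic values equal `sigma2_a` and
#' `sigma2_d` exactly, which gives parameter-recovery tests a well-defined
#' truth. Residuals are drawn from `N(0, sigma2_e)` without rescaling.
#'
#' @param g a [genotype_matrix].
#' @param mu intercept (trait units); default 0.
#' @param sigma2_a,sigma2_d,sigma2_e target additive, dominance and
#'   residual variances; defaults 2, 1, 1.
#' @param n_trials number of fixed "trial" groups individuals are randomly
#'   assigned to; default 1 (no trial effect).
#' @param trial_effects fixed effect of each trial; default: trials offset
#'   by one phenotypic standard deviation each, a strong batch effect.
#' @param seed integer seed (independent of the genotype seed).
#' @return list of class `sim_phenotypes`: `pheno` (data frame `id`,
#'   `trial`, `y`) and `truth` (marker effects `a`, `d`, genetic values
#'   `u_a`, `u_d`, residuals `e`, and realized variance components).
#' @export
simulate_phenotypes <- function(g, mu = 0, sigma2_a = 2, sigma2_d = 1,
                                sigma2_e = 1, n_trials = 1,
                                trial_effects = NULL, seed = 1) {
  stopifnot(sigma2_a >= 0, sigma2_d >= 0, sigma2_e >= 0)
  n <- nrow(g)
  codes <- unclass(g)
  Z <- codes - 1L            # 2/1/0 -> 1/0/-1
  S <- (codes == 1L) * 1
  Z[is.na(Z)] <- 0
  S[is.na(S)] <- 0
  seeds <- derive_seeds(seed, 3L)

  set.seed(seeds[1L])  # effects stream
  scale_to <- function(vals, target) {
    v <- stats::var(vals)
    if (target == 0 || v == 0) return(list(vals = vals * 0, factor = 0))
    f <- sqrt(target / v)
    list(vals = vals * f, factor = f)
  }
  a <- stats::rnorm(ncol(g))
  d <- stats::rnorm(ncol(g))
  ua <- scale_to(drop(Z %*% a), sigma2_a)
  ud <- scale_to(drop(S %*% d), sigma2_d)
  a <- a * ua$factor
  d <- d * ud$factor

  set.seed(seeds[2L])  # trial stream
  trial <- factor(sample.int(n_trials, n, replace = TRUE),
                  levels = seq_len(n_trials))
  if (is.null(trial_effects)) {
    trial_effects <- (seq_len(n_trials) - 1) *
      sqrt(sigma2_a + sigma2_d + sigma2_e)
  }
  stopifnot(length(trial_effects) == n_trials)

  set.seed(seeds[3L])  # noise stream
  e <- stats::rnorm(n, 0, sqrt(sigma2_e))
  y <- mu + trial_effects[as.integer(trial)] + ua$vals + ud$vals + e

  structure(list(
    pheno = data.frame(id = rownames(g), trial = trial, y = y,
                       stringsAsFactors = FALSE),
    truth = list(a = a, d = d, u_a = ua$vals, u_d = ud$vals, e = e,
                 mu = mu, trial_effects = trial_effects,
                 realized = c(sigma2_a = stats::var(ua$vals),
                              sigma2_d = stats::var(ud$vals),
                              sigma2_e = stats::var(e)))),
    class = "sim_phenotypes")
}
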