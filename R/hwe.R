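# Log conditional probability of each possible heterozygote count given the
# allele counts (Levene-Haldane distribution):
#   P(nAa | nA, na) = n! nA! na! 2^nAa / [ (2n)! nAA! nAa! naa! ]
hwe_het_distribution <- function(nA, na) {
  n <- (nA + na) / 2
  hets <- seq.int(nA %% 2L, min(nA, na), by = 2L)
  logp <- lfactorial(n) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n) -
    lfactorial((nA - hets) / 2) - lfactorial(hets) - lfactorial((na - hets) / 2) +
    hets * log(2)
  data.frame(nAa = hets, prob = exp(logp))
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' probability of every possible heterozygote count is fully enumerated and
#' the p-value is the sum of the probabilities of all configurations that are
#' no more probable than the observed one (ties included; no mid-p
#' correction).
#'
#' @param nAA,nAa,naa observed genotype counts at one marker.
#' @return the exact two-sided p-value in `(0, 1]`.
#' @examples
#' hwe_exact_test(1, 0, 1)  # 1/3
#' @export
hwe_exact_test <- function(nAA, nAa, naa) {
  if (length(nAA) != 1L || length(nAa) != 1L || length(naa) != 1L) {
    stop("hwe_exact_test takes scalar counts; use hwe_test() for a panel")
  }
  if (any(c(nAA, nAa, naa) < 0)) stop("genotype counts must be non-negative")
  if (nAA + nAa + naa < 1) stop("at least one observed genotype is required")
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1.0)  # monomorphic: single configuration
  d <- hwe_het_distribution(nA, na)
  p_obs <- d$prob[d$nAa == nAa]
  min(1, sum(d$prob[d$prob <= p_obs * (1 + 1e-12)]))
}

#' Hardy-Weinberg exact test and heterozygote excess for a genotype panel
#'
#' @param g a [genotype_matrix], or a `genotype_freqs` data frame carrying
#'   the genotype counts `nAA`, `nAa`, `naa`.
#' @return data frame with columns `marker`, `nAA`, `nAa`, `naa`, `p_value`
#'   and `het_excess` (`NA` where `2pq = 0`).
#' @export
hwe_test <- function(g) {
  f <- if (inherits(g, "genotype_matrix")) compute_frequencies(g) else g
  stopifnot(all(c("nAA", "nAa", "naa") %in% colnames(f)))
  pv <- mapply(hwe_exact_test, f$nAA, f$nAa, f$naa)
  he <- heterozygote_excess(f)
  data.frame(marker = f$marker, nAA = f$nAA, nAa = f$nAa, naa = f$naa,
             p_value = pv, het_excess = he$per_marker$het_excess,
             stringsAsFactors = FALSE)
}
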