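# Build a genotype-frequency table directly from proportions (the scale
# functions only need the proportions, p and q).
make_freqs <- function(pAA, pAa, paa) {
  stopifnot(all(abs(pAA + pAa + paa - 1) < 1e-12))
  k <- length(pAA)
  data.frame(marker = paste0("mk_", seq_len(k)),
             pAA = pAA, pAa = pAa, paa = paa,
             p = pAA + pAa / 2, q = paa + pAa / 2,
             stringsAsFactors = FALSE)
}

# k random genotype-frequency vectors uniform on the simplex.
rand_freqs <- function(k, seed = 1) {
  set.seed(seed)
  e <- matrix(stats::rexp(3 * k), k, 3)
  e <- e / rowSums(e)
  make_freqs(e[, 1], e[, 2], e[, 3])
}

triples_u <- function(s) as.matrix(s[, c("u_AA", "u_Aa", "u_aa")])
triples_v <- function(s) as.matrix(s[, c("v_AA", "v_Aa", "v_aa")])

write_geno_fixture <- function(rows, path, header) {
  writeLines(c(header, rows), path)
  path
}

# Brute-force oracle for the exact HWE test: enumerate every genotype
# configuration compatible with the observed allele counts and weight it by
# the number of distinct orderings times 2^(heterozygote count).
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1.0)
  configs <- list()
  for (h in 0:min(nA, na)) {
    if ((nA - h) %% 2 == 0 && (na - h) %% 2 == 0) {
      configs[[length(configs) + 1L]] <- c((nA - h) / 2, h, (na - h) / 2)
    }
  }
  w <- vapply(configs, function(cf) {
    exp(lfactorial(n) - sum(lfactorial(cf)) + cf[2] * log(2))
  }, numeric(1))
  probs <- w / sum(w)
  obs <- vapply(configs, function(cf) cf[2] == nAa, logical(1))
  sum(probs[probs <= probs[obs] * (1 + 1e-12)])
}
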