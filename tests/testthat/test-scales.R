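test_that("HW scale triples match their closed forms", {
  f <- make_freqs(pAA = c(0.25, 1, 0.0625),
                  pAa = c(0.5, 0, 0.375),
                  paa = c(0.25, 0, 0.5625))  # p = 0.5, 1, 0.25 under HWE
  s <- hw_scales(f)
  expect_equal(unname(triples_u(s)[1, ]), c(1, 0, -1))
  expect_equal(unname(triples_v(s)[1, ]), c(-0.5, 0.5, -0.5))
  expect_equal(unname(triples_u(s)[2, ]), c(0, -1, -2))
  expect_equal(s$sc_a_contrib[2], 0)
  expect_false(s$a_ok[2])
  expect_equal(unname(triples_u(s)[3, ]), c(1.5, 0.5, -0.5))
  expect_equal(s$sc_a_contrib[3], 0.375)
})

test_that("non-HWE scale triples match their closed forms and reduce to VanRaden at HWE", {
  s <- nohw_scales(make_freqs(0.5, 0.3, 0.2))
  expect_equal(unname(triples_u(s)[1, ]), c(0.7, -0.3, -1.3))
  expect_equal(s$sc_a_contrib, 0.61)
  expect_equal(s$sc_d_contrib, 0.3 - 0.09)

  # at HWE frequencies the additive triple equals the VanRaden triple
  p <- seq(0.05, 0.95, by = 0.05)
  fh <- make_freqs(p^2, 2 * p * (1 - p), (1 - p)^2)
  expect_equal(triples_u(nohw_scales(fh)), triples_u(hw_scales(fh)),
               tolerance = 1e-12)

  # all-heterozygous marker: dominance variance weight vanishes
  s2 <- nohw_scales(make_freqs(0, 1, 0))
  expect_equal(unname(triples_v(s2)[1, ]), c(-1, 0, -1))
  expect_equal(s2$sc_d_contrib, 0)
  expect_false(s2$d_ok)
})

test_that("NOIA dominance scales match the closed form and the HWE limit", {
  f <- make_freqs(0.5, 0.3, 0.2)
  s <- noia_scales(f)
  expect_equal(s$v_AA, -(2 * 0.3 * 0.2) / 0.61)
  expect_equal(s$v_Aa, (4 * 0.5 * 0.2) / 0.61)
  expect_equal(s$v_aa, -(2 * 0.5 * 0.3) / 0.61)
  # additive triple always equals the non-HWE triple
  fr <- rand_freqs(200, seed = 2)
  expect_equal(triples_u(noia_scales(fr)), triples_u(nohw_scales(fr)),
               tolerance = 1e-12)
  # HWE limit: NOIA dominance reduces to the classical dominance-deviation
  # coding (-2q^2, 2pq, -2p^2) with per-marker weight (2pq)^2; at p = 0.5
  # this coincides with the biological HW triple
  expect_equal(unname(triples_v(noia_scales(make_freqs(0.25, 0.5, 0.25)))[1, ]),
               c(-0.5, 0.5, -0.5))
  p <- seq(0.1, 0.9, by = 0.1)
  q <- 1 - p
  fh <- make_freqs(p^2, 2 * p * q, q^2)
  sh <- noia_scales(fh)
  expect_equal(triples_v(sh),
               cbind(-2 * q^2, 2 * p * q, -2 * p^2),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sh$sc_d_contrib, (2 * p * q)^2, tolerance = 1e-12)
  # the NO-HW dominance weight is the one that reduces to 2pq(1 - 2pq)
  expect_equal(nohw_scales(fh)$sc_d_contrib,
               2 * p * q * (1 - 2 * p * q), tolerance = 1e-12)
})

test_that("GSP-A projection reproduces the NOIA dominance scales and expected traces", {
  fr <- rand_freqs(1000, seed = 3)
  sa <- gspa_scales(fr)
  sn <- noia_scales(fr)
  ok <- sa$d_ok
  expect_true(any(ok))
  expect_lt(max(abs(triples_v(sa)[ok, ] - triples_v(sn)[ok, ])), 1e-10)
  # equal homozygote frequencies: projection coefficient is zero
  s0 <- gspa_scales(make_freqs(0.4, 0.2, 0.4))
  expect_equal(unname(triples_v(s0)[1, ]), c(-0.2, 0.8, -0.2))
  # frozen expected dominance trace contribution
  expect_equal(gspa_scales(make_freqs(0.5, 0.3, 0.2))$sc_d_contrib,
               4 * 0.5 * 0.3 * 0.2 / 0.61)
  # realized-vs-expected identity: sc_d equals the frequency-weighted sum of
  # squared dominance entries
  w <- cbind(fr$pAA, fr$pAa, fr$paa)
  realized <- rowSums(w * triples_v(sa)^2)
  expect_lt(max(abs(realized[ok] - sa$sc_d_contrib[ok])), 1e-10)
})

test_that("GSP-D scales match their closed forms with zero heterozygote additive entry", {
  s <- gspd_scales(make_freqs(0.5, 0.3, 0.2))
  expect_equal(unname(triples_u(s)[1, ]), c(2 * 0.2 / 0.7, 0, -2 * 0.5 / 0.7))
  expect_equal(s$sc_a_contrib, 4 * 0.5 * 0.2 / 0.7)
  expect_equal(s$sc_d_contrib, 0.21)
  s2 <- gspd_scales(make_freqs(0.25, 0.5, 0.25))
  expect_equal(unname(triples_u(s2)[1, ]), c(1, 0, -1))
  fr <- rand_freqs(500, seed = 4)
  expect_true(all(gspd_scales(fr)$u_Aa == 0))
  # all-heterozygous marker has no additive scale
  expect_false(gspd_scales(make_freqs(0, 1, 0))$a_ok)
})

test_that("GSP-N scales are unit-norm and carry the frozen norm value", {
  f <- make_freqs(0.5, 0.3, 0.2)
  expect_equal(sqrt(100 * gspa_scales(f)$sc_a_contrib), sqrt(61),
               tolerance = 1e-12)  # ||tau_A|| at n = 100
  fr <- rand_freqs(300, seed = 5)
  n <- 57
  s <- gspn_scales(fr, n)
  w <- cbind(fr$pAA, fr$pAa, fr$paa)
  norm_a <- n * rowSums(w * triples_u(s)^2)
  norm_d <- n * rowSums(w * triples_v(s)^2)
  expect_lt(max(abs(norm_a[s$a_ok] - 1)), 1e-10)
  expect_lt(max(abs(norm_d[s$d_ok] - 1)), 1e-10)
})

test_that("additive triples keep the unit allele-substitution structure", {
  fr <- rand_freqs(400, seed = 6)
  for (fn in list(nohw_scales, noia_scales, gspa_scales)) {
    u <- triples_u(fn(fr))
    expect_lt(max(abs(u[, 1] - u[, 2] - 1)), 1e-12)
    expect_lt(max(abs(u[, 2] - u[, 3] - 1)), 1e-12)
  }
})

test_that("orthogonality conditions hold for the orthogonal methods only", {
  fr <- rand_freqs(1000, seed = 7)
  n_ind <- 20
  for (method in c("NOIA", "GSP-A", "GSP-D", "GSP-N")) {
    s <- marker_scales(fr, method, n = n_ind)
    res <- verify_orthogonality(s, fr)
    ok <- s$a_ok & s$d_ok
    expect_lt(max(abs(res$mean_additive[ok])), 1e-10)
    expect_lt(max(abs(res$mean_dominance[ok])), 1e-10)
    expect_lt(max(abs(res$cross_product[ok])), 1e-10)
    expect_true(attr(res, "orthogonal"))
  }
  # non-HWE scales are centered but not orthogonal
  f <- make_freqs(0.5, 0.3, 0.2)
  res <- verify_orthogonality(nohw_scales(f), f)
  expect_lt(abs(res$mean_additive), 1e-12)
  expect_lt(abs(res$mean_dominance), 1e-12)
  expect_equal(res$cross_product, (-0.3) * (0.5 - 0.2))
  expect_false(attr(res, "orthogonal"))
})

test_that("marker angle matches an explicit vector-space oracle", {
  # oracle: build the literal 100-individual scale vectors and measure the
  # angle numerically
  n <- 100
  counts <- c(AA = 50, Aa = 30, aa = 20)
  f <- make_freqs(0.5, 0.3, 0.2)
  s <- nohw_scales(f)
  u_vec <- rep(c(s$u_AA, s$u_Aa, s$u_aa), counts)
  v_vec <- rep(c(s$v_AA, s$v_Aa, s$v_aa), counts)
  cos_oracle <- sum(u_vec * v_vec) /
    (sqrt(sum(u_vec^2)) * sqrt(sum(v_vec^2)))
  ang <- marker_angle(f, n = n)
  expect_equal(ang$cos_theta, cos_oracle, tolerance = 1e-12)
  expect_equal(ang$cos_theta, -0.09 / sqrt(0.61 * 0.21), tolerance = 1e-10)
  expect_equal(ang$theta_degrees, 104.5639, tolerance = 1e-4)
  expect_equal(ang$inner_product, sum(u_vec * v_vec), tolerance = 1e-10)
})

test_that("the angle is 90 degrees exactly when homozygote frequencies are equal", {
  grid <- expand.grid(hom = seq(0.05, 0.45, by = 0.05))
  f_eq <- make_freqs(grid$hom, 1 - 2 * grid$hom, grid$hom)
  expect_equal(marker_angle(f_eq)$theta_degrees, rep(90, nrow(f_eq)),
               tolerance = 1e-10)
  # and only then (given heterozygotes present): unequal homozygotes tilt it
  fr <- rand_freqs(300, seed = 8)
  ang <- marker_angle(fr)
  defined <- !is.na(ang$theta_degrees)
  off <- abs(fr$pAA - fr$paa) > 1e-6 & fr$pAa > 1e-6
  expect_true(all(abs(ang$theta_degrees[defined & off] - 90) > 1e-8))
})

test_that("the angle does not depend on the number of individuals", {
  fr <- rand_freqs(50, seed = 9)
  expect_equal(marker_angle(fr, n = 10)$theta_degrees,
               marker_angle(fr, n = 10000)$theta_degrees)
})

test_that("scale matrices center columns and handle missing genotypes and degeneracy", {
  # two individuals AA and aa, one marker, NO-HW: column (1, -1), SC_a = 1
  g <- genotype_matrix(matrix(c(2, 0), ncol = 1), ids = c("a", "b"),
                       markers = "m1")
  sm <- build_scale_matrices(g, "nohw")
  expect_equal(unname(sm$Ha[, 1]), c(1, -1))
  expect_equal(sm$SC_a, 1)

  # complete data: column sums of Ha and Hd are exactly zero
  gp <- simulate_genotypes(n = 60, m = 120, seed = 10)
  for (method in c("nohw", "noia", "gspa", "gspd", "gspn")) {
    smp <- build_scale_matrices(gp, method)
    expect_lt(max(abs(colSums(smp$Ha))), 1e-10)
    expect_lt(max(abs(colSums(smp$Hd))), 1e-10)
  }

  # missing genotypes enter as 0 after centering, keeping column sums zero
  gm <- simulate_genotypes(n = 60, m = 120, missing_rate = 0.1, seed = 10)
  smm <- build_scale_matrices(gm, "nohw")
  expect_lt(max(abs(colSums(smm$Ha))), 1e-10)
  expect_true(all(smm$Ha[is.na(unclass(gm))] == 0))

  # HW dominance centering fails off-HWE: column mean is pAa - 2pq
  g1 <- genotype_matrix(matrix(1, 4, 1), ids = letters[1:4], markers = "m1")
  smh <- build_scale_matrices(g1, "hw")
  expect_equal(mean(smh$Hd[, 1]), 0.5)  # pAa - 2pq = 1 - 0.5

  # monomorphic-only panel is an error
  g0 <- genotype_matrix(matrix(2, 5, 2), ids = letters[1:5],
                        markers = c("m1", "m2"))
  expect_error(build_scale_matrices(g0, "noia"), "degenerate")
  expect_error(build_grm(build_scale_matrices(
    genotype_matrix(matrix(c(2, 2, 2, 2, 2, 0), 3, 2),
                    ids = letters[1:3], markers = c("m1", "m2")), "nohw"),
    "dominance"), "denominator")
})

test_that("degenerate markers are excluded and logged by id", {
  g <- genotype_matrix(cbind(m1 = c(2, 1, 0, 1), m2 = c(2, 2, 2, 2),
                             m3 = c(1, 1, 1, 1)),
                       ids = letters[1:4])
  sm <- build_scale_matrices(g, "noia")
  expect_setequal(sm$excluded_additive, c("m2", "m3"))
  expect_true(all(c("m2", "m3") %in% sm$excluded_dominance))
  expect_true(all(sm$Ha[, "m2"] == 0))
})

test_that("method names are normalized and unknown methods rejected", {
  f <- make_freqs(0.5, 0.3, 0.2)
  expect_identical(attr(marker_scales(f, "gspa"), "method"), "GSP-A")
  expect_identical(attr(marker_scales(f, "NO-HW"), "method"), "NO-HW")
  expect_error(marker_scales(f, "bogus"), "valid methods")
})
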