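# Beta-mixture EM, the strength-conditioned length model, and the
# five-component exon-definition score.

test_that("EM recovers single-Beta parameters and keeps likelihood monotone", {
  set.seed(2025)
  x <- rbeta(5000, 2, 5)
  fit <- fit_beta_mixture(x, k = 1)
  expect_lt(abs(fit$alphas - 2) / 2, 0.10)
  expect_lt(abs(fit$betas - 5) / 5, 0.10)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("EM recovers an equal two-component mixture", {
  set.seed(99)
  x <- c(rbeta(5000, 2, 20), rbeta(5000, 10, 4))
  fit <- fit_beta_mixture(x, k = 2)
  expect_equal(fit$k, 2L)
  expect_lt(max(abs(sort(fit$weights) - 0.5)), 0.05)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # component means recover the two modes (order-free)
  means <- sort(fit$alphas / (fit$alphas + fit$betas))
  expect_equal(means, c(2 / 22, 10 / 14), tolerance = 0.1)
})

test_that("EM rejects degenerate and insufficient data", {
  expect_error(fit_beta_mixture(rep(0.4, 100), k = 1), "degenerate")
  expect_error(fit_beta_mixture(runif(5), k = 1), "insufficient")
  expect_error(fit_beta_mixture(c(0, runif(99)), k = 1), "strictly")
})

test_that("single-component EM agrees with an independent Beta MLE", {
  skip_if_not_installed("fitdistrplus")
  set.seed(7)
  x <- rbeta(3000, 3, 8)
  ours <- fit_beta_mixture(x, k = 1)
  ref <- fitdistrplus::fitdist(x, "beta")
  expect_equal(unname(ours$alphas), unname(ref$estimate["shape1"]),
               tolerance = 1e-3)
  expect_equal(unname(ours$betas), unname(ref$estimate["shape2"]),
               tolerance = 1e-3)
})

test_that("mixture density integrates to one", {
  set.seed(13)
  fit <- fit_beta_mixture(c(rbeta(600, 2, 9), rbeta(400, 8, 3)), k = 2)
  q <- stats::integrate(function(z) dbeta_mixture(z, fit), 0, 1,
                        rel.tol = 1e-9)
  expect_equal(q$value, 1, tolerance = 1e-6)
})

test_that("length LOD is the log2 density ratio against the uniform law", {
  um <- uniform_length_model()
  expect_equal(length_lod(um, 1, 1, 50), 0)
  expect_equal(length_lod(um, 5, 5, 399), 0)
  expect_error(length_lod(um, 3, 3, 0), "strictly")
  expect_error(length_lod(um, 3, 3, 400), "strictly")

  # closed-form oracle: a Beta(2,5) cell scores log2 dbeta(size/400, 2, 5)
  bm <- structure(list(k = 1L, weights = 1, alphas = 2, betas = 5,
                       loglik = NA_real_, loglik_trace = NULL,
                       n_iter = 0L, n_obs = 0L), class = "beta_mixture")
  lm <- uniform_length_model()
  lm$grid <- rep(list(bm), length(lm$grid))
  mode_nt <- 400 * (2 - 1) / (2 + 5 - 2)  # Beta mode on the nt scale
  expect_equal(length_lod(lm, 2, 4, mode_nt),
               log2(dbeta(mode_nt / 400, 2, 5)), tolerance = 1e-12)
})

test_that("strength-conditioned fits give strong-strong cells shorter exons", {
  set.seed(31)
  strong <- pmin(pmax(round(400 * rbeta(300, 2.5, 1 + 0.7 * 10)), 30), 399)
  weak <- pmin(pmax(round(400 * rbeta(300, 2.5, 1 + 0.7 * 2)), 30), 399)
  lengths <- c(strong, weak)
  s3 <- rep(c(5L, 1L), each = 300)
  s5 <- rep(c(5L, 1L), each = 300)
  lm <- fit_length_model(lengths, s3, s5, k = 2, min_cell = 50)
  grid_nt <- 1:399
  peak <- function(a, b) grid_nt[which.max(vapply(grid_nt, function(s) {
    length_lod(lm, a, b, s)
  }, numeric(1)))]
  expect_lt(peak(5, 5), peak(1, 1))
  # sparse cells borrow the nearest populated fit rather than failing
  expect_equal(length_lod(lm, 5, 4, 100), length_lod(lm, 5, 5, 100))
})

test_that("exon score is the exact sum of its five components", {
  acc <- make_call(100, kind = "acceptor", posterior = 0.5)
  don <- make_call(180, kind = "donor_GT", posterior = 0.5)
  neutral <- score_exon(acc, don, length_model = uniform_length_model())
  expect_equal(neutral$total_lod, 0)
  expect_equal(neutral$length, 80L)

  # additivity: one +0.6 enhancer raises the total by exactly 0.6
  hit <- make_hit(120, 0.6)
  with_hit <- score_exon(acc, don, element_hits = hit,
                         length_model = uniform_length_model())
  expect_equal(with_hit$total_lod - neutral$total_lod, 0.6,
               tolerance = 1e-12)

  # audited component-sum oracle with all five terms active
  set.seed(41)
  acc2 <- make_call(100, kind = "acceptor", posterior = 0.9, strength = 4L)
  don2 <- make_call(300, kind = "donor_GT", posterior = 0.8, strength = 5L)
  hits <- rbind(make_hit(150, 1.1), make_hit(200, -0.3))
  comp <- make_call(320, kind = "donor_GT", posterior = 0.95)
  ex <- score_exon(acc2, don2, element_hits = hits, competitor_hits = comp,
                   length_model = uniform_length_model(),
                   competitor_scale = 0.5)
  by_hand <- log2(0.9 / 0.1) + log2(0.8 / 0.2) + 0 + (1.1 - 0.3) +
    (-0.5 * log2(0.95 / 0.05))
  expect_equal(ex$total_lod, by_hand, tolerance = 1e-9)
  expect_equal(ex$total_lod,
               ex$lod_acceptor + ex$lod_donor + ex$lod_length +
                 ex$lod_elements + ex$lod_competitors, tolerance = 1e-12)
})

test_that("exon score grows with either site posterior", {
  acc <- make_call(0, kind = "acceptor", posterior = 0.5)
  totals <- vapply(seq(0.05, 0.95, by = 0.1), function(p) {
    don <- make_call(90, kind = "donor_GT", posterior = p)
    score_exon(acc, don, length_model = uniform_length_model())$total_lod
  }, numeric(1))
  expect_true(all(diff(totals) > 0))
  don <- make_call(90, kind = "donor_GT", posterior = 0.5)
  totals3 <- vapply(seq(0.05, 0.95, by = 0.1), function(p) {
    a <- make_call(0, kind = "acceptor", posterior = p)
    score_exon(a, don, length_model = uniform_length_model())$total_lod
  }, numeric(1))
  expect_true(all(diff(totals3) > 0))
})

test_that("exon scoring rejects malformed pairs", {
  acc <- make_call(100, kind = "acceptor")
  expect_error(score_exon(acc, make_call(90)), "downstream")
  expect_error(score_exon(acc, make_call(103)), "length")
  expect_error(score_exon(acc, make_call(520)), "length")
})

test_that("normalized exon score follows the reference LOD distribution", {
  acc <- make_call(0, kind = "acceptor", posterior = 0.9)
  don <- make_call(100, kind = "donor_GT", posterior = 0.9)
  cal <- list(default = seq(-10, 10, by = 0.5))
  lo <- score_exon(make_call(0, kind = "acceptor", posterior = 0.1),
                   make_call(100), exon_calibration = cal)
  hi <- score_exon(acc, don, exon_calibration = cal)
  expect_gt(hi$normalized_exon_score, lo$normalized_exon_score)
  expect_true(hi$normalized_exon_score > 0 && hi$normalized_exon_score < 1)
})
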