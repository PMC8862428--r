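det <- activator_params(k = 17.58, K_T = 0.82, K_S = 13.34,
                        alpha = 1.03, beta = 8.30)
nd <- activator_params(k = 31.86, K_T = 1.41, K_S = 9.65,
                       alpha = 10.05, beta = 76.60)
pl <- activator_params(k = 9.49, K_T = 1.64, K_S = 12.79,
                       alpha = 2.64, beta = 28.69)

test_that("parameter constructors reject non-positive or non-finite values", {
  expect_error(michaelis_params(-1, 1), "invalid-parameter")
  expect_error(michaelis_params(1, 0), "invalid-parameter")
  expect_error(activator_params(1, 1, 1, NA, 1), "invalid-parameter")
  expect_error(activator_params(1, 1, Inf, 1, 1), "invalid-parameter")
  expect_error(activator_params(1, 1, 1, 1, 1e-15), "invalid-parameter")
})

test_that("Michaelis-Menten rate: half-saturation, hand value, limits", {
  p <- michaelis_params(kcat = 7.3, Km = 2.1)
  expect_equal(mm_rate(p, T = 2.1), 7.3 / 2)
  expect_equal(mm_rate(michaelis_params(10, 1), T = 4), 8.0)
  expect_equal(mm_rate(p, T = 0), 0)
  expect_equal(mm_rate(michaelis_params(18.0, 0.82), T = 1e9), 18.0,
               tolerance = 1e-6)
  expect_error(mm_rate(p, T = -1), "invalid-concentration")
})

test_that("activator velocity: zero at T=0, decouples at alpha=beta=1, saturates at k", {
  expect_equal(activator_velocity(det, T = 0, S = c(0, 1, 5, 20)),
               rep(0, 4))
  p1 <- activator_params(k = 12, K_T = 0.7, K_S = 9, alpha = 1, beta = 1)
  mm <- michaelis_params(kcat = 12, Km = 0.7)
  Tg <- c(0, 0.1, 0.5, 2, 10); Sg <- c(0, 1, 5, 20)
  for (S in Sg) {
    expect_equal(activator_velocity(p1, Tg, S), mm_rate(mm, Tg),
                 tolerance = 1e-12)
  }
  # E_total scales the specific rate linearly
  expect_equal(activator_velocity(det, 2, 5, E_total = 3.7e-7),
               3.7e-7 * activator_velocity(det, 2, 5))
  # basal saturating MgATP recovers the basal rate constant
  expect_equal(activator_velocity(det, T = 1e9, S = 0), 17.58,
               tolerance = 1e-6)
  expect_equal(activator_velocity(det, T = 10, S = 0), 16.24769,
               tolerance = 1e-6)
})

test_that("kobs matches direct arithmetic and its limits", {
  expect_equal(kobs(det, 0), 17.58)
  expect_equal(kobs(nd, 20), 443.6508, tolerance = 1e-6)
  expect_equal(kobs(pl, 20), 107.2395, tolerance = 1e-6)
  # beta = 1 turns stimulation off entirely
  pb1 <- activator_params(5, 1, 10, 2, 1)
  expect_equal(kobs(pb1, c(0, 1, 10, 100)), rep(5, 4))
  # S -> infinity limit is beta * k (checked at S = 1e6 * K_S)
  for (p in list(det, nd, pl)) {
    expect_equal(kobs(p, 1e6 * p$K_S), p$beta * p$k,
                 tolerance = 1e-3)
  }
})

test_that("kt_app matches direct arithmetic, is constant at alpha=1, limits at alpha*K_T", {
  expect_equal(kt_app(det, 0), 0.82)
  expect_equal(kt_app(det, 20), 0.834582, tolerance = 1e-6)
  pa1 <- activator_params(5, 0.9, 10, 1, 4)
  expect_equal(kt_app(pa1, c(0, 2, 20, 200)), rep(0.9, 4))
  for (p in list(det, nd, pl)) {
    expect_equal(kt_app(p, 1e6 * p$K_S), p$alpha * p$K_T,
                 tolerance = 1e-3)
  }
})

test_that("fold stimulation reproduces the published ~5, ~14, ~11 factors", {
  expect_equal(fold_stimulation(det, 0), 1)
  expect_equal(fold_stimulation(det, 20), 5.327182, tolerance = 1e-6)
  expect_equal(fold_stimulation(pl, 20), 11.30027, tolerance = 1e-6)
  expect_identical(round(fold_stimulation(det, 20)), 5)
  expect_identical(round(fold_stimulation(nd, 20)), 14)
  expect_identical(round(fold_stimulation(pl, 20)), 11)
  # bounded above by beta
  for (p in list(det, nd, pl)) {
    expect_lt(fold_stimulation(p, 1e8), p$beta + 1e-6)
  }
})

test_that("factorization identity ties velocity, kobs and kt_app together", {
  Tg <- c(0, 0.1, 0.7, 3, 11)
  Sg <- c(0, 0.4, 2, 9, 40)
  for (p in random_params(50)) {
    v <- outer(Tg, Sg, function(T, S) activator_velocity(p, T, S))
    v2 <- outer(Tg, Sg, function(T, S) kobs(p, S) * T / (kt_app(p, S) + T))
    expect_equal(v, v2, tolerance = 1e-10)
  }
})

test_that("kobs and kt_app are monotone non-decreasing in S when beta, alpha >= 1", {
  Sg <- seq(0, 200, length.out = 400)
  for (p in random_params(30, seed = 7)) {
    if (p$beta >= 1) expect_true(all(diff(kobs(p, Sg)) >= -1e-12))
    if (p$alpha >= 1) expect_true(all(diff(kt_app(p, Sg)) >= -1e-12))
    # and alpha < 1 makes kt_app decrease (positive cooperativity)
    if (p$alpha < 1) expect_true(all(diff(kt_app(p, Sg)) <= 1e-12))
  }
})

test_that("alpha = beta = 1 makes the velocity independent of S", {
  p <- activator_params(k = 23, K_T = 1.3, K_S = 6, alpha = 1, beta = 1)
  Tg <- c(0.2, 1, 5)
  Sg <- seq(0, 50, length.out = 40)
  for (T in Tg) {
    v <- activator_velocity(p, T, Sg)
    expect_lt(max(abs(v / v[1] - 1)), 1e-12)
  }
})
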