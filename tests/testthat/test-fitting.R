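det_p <- naatm1_params("detergent")
det_ctx <- reconstitution_context("detergent")

test_that("extract_rate recovers an exact line and round-trips the model", {
  tc <- tibble::tibble(condition = "detergent", atp_mM = 1, gssg_mM = 0,
                       replicate = 1L, time_min = c(0, 5, 10, 15),
                       pi_uM = 2.5 * c(0, 5, 10, 15) + 1)
  r <- extract_rate(tc, det_ctx)
  expect_equal(r$rate_per_min, 2.5 / (transporter_molarity(det_ctx) * 1e6))
  # noise-free simulated course round-trips the activator velocity
  tc2 <- simulate_timecourse(det_p, det_ctx, 5, 10, noise = noise_spec(0, 0))
  expect_equal(extract_rate(tc2, det_ctx)$rate_per_min,
               activator_velocity(det_p, 5, 10), tolerance = 1e-10)
  tc3 <- tc[c(1, 1), ]
  expect_error(extract_rate(tc3, det_ctx), "degenerate-timecourse")
})

test_that("Michaelis-Menten fit recovers exact parameters and rejects degenerate data", {
  Tg <- c(0, 0.1, 0.2, 0.5, 1, 2, 5, 10)
  obs <- tibble::tibble(atp_mM = Tg,
                        rate_per_min = mm_rate(michaelis_params(18.0, 0.82), Tg))
  fit <- fit_michaelis(obs)
  expect_equal(fit$estimates[["kcat"]], 18.0, tolerance = 1e-6)
  expect_equal(fit$estimates[["Km"]], 0.82, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_error(fit_michaelis(tibble::tibble(atp_mM = Tg,
                                            rate_per_min = rep(0, 8))),
               "degenerate-data")
  expect_error(fit_michaelis(obs[1:2, ]), "degenerate-data")
  expect_error(fit_michaelis(tibble::tibble(atp_mM = Tg, gssg_mM = Tg,
                                            rate_per_min = Tg)),
               "design error")
})

test_that("Michaelis standard errors match the nls asymptotic covariance", {
  Tg <- c(0.1, 0.2, 0.5, 1, 2, 5, 10)
  y <- mm_rate(michaelis_params(18.0, 0.82), Tg) *
    (1 + withr::with_seed(5, rnorm(7, 0, 0.03)))
  obs <- tibble::tibble(atp_mM = Tg, rate_per_min = y)
  fit <- fit_michaelis(obs)
  ref <- stats::nls(rate_per_min ~ kcat * atp_mM / (Km + atp_mM), data = obs,
                    start = list(kcat = 18, Km = 0.8))
  expect_equal(unname(fit$estimates), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(unname(fit$standard_errors),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-3)
})

test_that("per-GSSG Michaelis fits of noise-free activator data equal kobs and kt_app", {
  d <- noisefree_dataset("detergent")
  for (s in c(0, 5, 20)) {
    fit <- fit_michaelis(d[d$gssg_mM == s, ])
    expect_equal(fit$estimates[["kcat"]], kobs(det_p, s), tolerance = 1e-6)
    expect_equal(fit$estimates[["Km"]], kt_app(det_p, s), tolerance = 1e-6)
  }
  # frozen arithmetic for the top activator level
  fit20 <- fit_michaelis(d[d$gssg_mM == 20, ])
  expect_equal(fit20$estimates[["kcat"]], 93.65187, tolerance = 1e-5)
  expect_equal(fit20$estimates[["Km"]], 0.834582, tolerance = 1e-5)
})

test_that("global activator fit recovers all five parameters exactly on noise-free data", {
  for (cond in paper_conditions) {
    truth <- unlist(unclass(naatm1_params(cond)))
    fit <- fit_activator_global(noisefree_dataset(cond))
    expect_true(fit$converged)
    expect_equal(unname(fit$estimates[names(truth)]), unname(truth),
                 tolerance = 1e-3)
    # the global minimum is reachable from every restart on this design
    expect_equal(fit$n_restarts_used, 16L)
    expect_true(all(fit$restarts$ssr < 1e-8))
    # asymptotic uncertainty collapses without noise
    expect_true(all(fit$standard_errors / fit$estimates < 1e-5))
    expect_equal(fit$r_squared$global, 1, tolerance = 1e-10)
  }
})

test_that("global fit demands a usable design", {
  d <- noisefree_dataset("detergent")
  expect_error(fit_activator_global(d[d$gssg_mM == 20, ]), "design error")
  expect_error(fit_activator_global(d[d$gssg_mM > 0, ]), "design error")
  expect_error(fit_activator_global(d[d$atp_mM %in% c(0, 10), ]),
               "design error")
})

test_that("fit result covariance is symmetric PSD and R-squared is bounded", {
  fit <- fit_activator_global(noisy_dataset("detergent", seed = 3))
  expect_true(isSymmetric(fit$covariance))
  expect_true(all(eigen(fit$covariance, only.values = TRUE)$values > -1e-8))
  expect_true(all(fit$standard_errors >= 0))
  expect_lte(fit$r_squared$global, 1)
  expect_true(all(fit$r_squared$per_curve$r_squared <= 1))
  expect_equal(fit$n_points, 48L)
})

test_that("optimizer beats a coarse brute-force log-grid search", {
  for (seed in c(2, 6)) {
    obs <- noisy_dataset("detergent", seed = seed)
    m <- aggregate(rate_per_min ~ atp_mM + gssg_mM, obs, mean)
    fit <- fit_activator_global(obs)
    ssr_fit <- sum(fit$residuals^2)
    truth <- unlist(unclass(det_p))
    axes <- lapply(truth, function(v) exp(seq(log(v / 4), log(v * 4),
                                              length.out = 5)))
    grid <- do.call(expand.grid, axes)
    ssr_grid <- apply(grid, 1, function(q) {
      v <- activator_velocity(activator_params(q[1], q[2], q[3], q[4], q[5]),
                              m$atp_mM, m$gssg_mM)
      sum((v - m$rate_per_min)^2)
    })
    expect_lte(ssr_fit, min(ssr_grid))
  }
})

test_that("data generated without activation fit back to alpha, beta near 1", {
  p1 <- activator_params(k = 17.58, K_T = 0.82, K_S = 13.34,
                         alpha = 1, beta = 1)
  # noise-free: the reduction is exact, so the activator fit collapses onto
  # the plain Michaelis-Menten fit of the pooled data
  exact <- simulate_dataset(p1, det_ctx, paper_design("detergent"),
                            noise = noise_spec(0, 0), seed = 10)
  fit0 <- fit_activator_global(exact)
  expect_equal(fit0$estimates[["alpha"]], 1, tolerance = 1e-4)
  expect_equal(fit0$estimates[["beta"]], 1, tolerance = 1e-4)
  pooled0 <- fit_michaelis(tibble::tibble(atp_mM = exact$atp_mM,
                                          rate_per_min = exact$rate_per_min))
  expect_equal(fit0$estimates[["k"]], pooled0$estimates[["kcat"]],
               tolerance = 0.01)
  expect_equal(fit0$estimates[["K_T"]], pooled0$estimates[["Km"]],
               tolerance = 0.01)
  # with noise the activation directions are flat ridges, so the asymptotic
  # intervals blow up and still cover the no-activation values
  obs <- simulate_dataset(p1, det_ctx, paper_design("detergent"),
                          noise = noise_spec(cv = 0.05), seed = 10)
  fit <- fit_activator_global(obs)
  for (nm in c("alpha", "beta")) {
    lo <- fit$estimates[[nm]] - 2 * fit$standard_errors[[nm]]
    hi <- fit$estimates[[nm]] + 2 * fit$standard_errors[[nm]]
    expect_true(lo <= 1 && 1 <= hi)
  }
  expect_equal(fit$estimates[["k"]], 17.58, tolerance = 0.05)
  expect_equal(fit$estimates[["K_T"]], 0.82, tolerance = 0.05)
})

test_that("derived curves report kobs, kt_app and fold on observed and dense grids", {
  fit <- fit_activator_global(noisefree_dataset("proteoliposomes"))
  dc <- derived_curves(fit)
  obs_rows <- dc[dc$grid == "observed", ]
  expect_equal(obs_rows$gssg_mM, c(0, 1, 2.5, 5, 10, 20))
  expect_equal(obs_rows$kobs[1], fit$estimates[["k"]], tolerance = 1e-6)
  expect_equal(obs_rows$kt_app[1], fit$estimates[["K_T"]], tolerance = 1e-6)
  expect_equal(obs_rows$fold[1], 1, tolerance = 1e-9)
  expect_equal(obs_rows$kobs[obs_rows$gssg_mM == 20], 107.2395,
               tolerance = 1e-3)
  expect_equal(obs_rows$fold_nearest[obs_rows$gssg_mM == 20], 11)
  # parameters can be passed directly
  dc2 <- derived_curves(naatm1_params("nanodiscs"), s_levels = 20,
                        dense_n = 0)
  expect_equal(dc2$fold_nearest, 14)
})
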