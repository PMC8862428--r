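det_p <- naatm1_params("detergent")
det_ctx <- reconstitution_context("detergent")

test_that("noise-free time courses are exactly linear with the model slope", {
  tc <- simulate_timecourse(det_p, det_ctx, atp = 10, gssg = 0,
                            noise = noise_spec(0, 0))
  E_uM <- transporter_molarity(det_ctx) * 1e6
  slope <- unname(coef(lm(pi_uM ~ time_min, tc))[2])
  expect_equal(slope / E_uM, 16.24769, tolerance = 1e-6)
  expect_equal(tc$pi_uM, activator_velocity(det_p, 10, 0) * E_uM * tc$time_min)
})

test_that("simulation is bitwise reproducible under a fixed seed", {
  a <- simulate_timecourse(det_p, det_ctx, 2, 5, seed = 99)
  b <- simulate_timecourse(det_p, det_ctx, 2, 5, seed = 99)
  expect_identical(a, b)
  d1 <- simulate_dataset(det_p, det_ctx, paper_design("detergent"), seed = 4)
  d2 <- simulate_dataset(det_p, det_ctx, paper_design("detergent"), seed = 4)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(det_p, det_ctx, paper_design("detergent"), seed = 5)
  expect_false(identical(d1$rate_per_min, d3$rate_per_min))
})

test_that("datasets have one rate per grid cell and replicate", {
  d <- simulate_dataset(det_p, det_ctx, paper_design("detergent"), seed = 1)
  expect_equal(nrow(d), 8 * 6 * 6)
  nd <- simulate_dataset(naatm1_params("nanodiscs"),
                         reconstitution_context("nanodiscs"),
                         paper_design("nanodiscs"), seed = 1)
  expect_equal(nrow(nd), 8 * 6 * 3)
  expect_equal(nrow(unique(nd[c("atp_mM", "gssg_mM", "replicate")])), 144L)
})

test_that("noise-free simulated mean rates equal the model velocity at every grid point", {
  d <- noisefree_dataset("detergent")
  means <- aggregate(rate_per_min ~ atp_mM + gssg_mM, d, mean)
  expect_equal(means$rate_per_min,
               activator_velocity(det_p, means$atp_mM, means$gssg_mM),
               tolerance = 1e-10)
  # replicates are identical without noise
  spread <- aggregate(rate_per_min ~ atp_mM + gssg_mM, d,
                      function(x) diff(range(x)))
  expect_lt(max(spread$rate_per_min), 1e-10)
})

test_that("empirical replicate CV at high signal approaches the configured cv", {
  grid <- design_grid(atp = c(0, 10), gssg = c(0, 20), n_replicates = 200,
                      time_points = c(0, 5, 10, 15))
  d <- simulate_dataset(det_p, det_ctx, grid, noise = noise_spec(cv = 0.05),
                        seed = 8)
  hi <- d[d$atp_mM == 10 & d$gssg_mM == 20, ]
  cv_emp <- sd(hi$rate_per_min) / mean(hi$rate_per_min)
  expect_lt(abs(cv_emp / 0.05 - 1), 0.30)
})

test_that("alpha = beta = 1 leaves mean rates flat across GSSG within noise", {
  p1 <- activator_params(k = 17.58, K_T = 0.82, K_S = 13.34,
                         alpha = 1, beta = 1)
  d <- simulate_dataset(p1, det_ctx, paper_design("detergent"),
                        noise = noise_spec(cv = 0.05), seed = 2)
  hi <- d[d$atp_mM == 10, ]
  means <- aggregate(rate_per_min ~ gssg_mM, hi, mean)
  expect_lt(diff(range(means$rate_per_min)) / mean(means$rate_per_min), 0.1)
})

test_that("noise specification and t0 flag behave as documented", {
  expect_error(noise_spec(cv = -0.1), "invalid-noise")
  expect_error(noise_spec(additive_floor = -1), "invalid-noise")
  tc <- simulate_timecourse(det_p, det_ctx, 1, 0, noise = noise_spec(),
                            seed = 3, measure_t0 = FALSE)
  expect_equal(tc$pi_uM[tc$time_min == 0], 0)
  expect_true(all(simulate_timecourse(det_p, det_ctx, 1, 0,
                                      seed = 3)$pi_uM >= 0))
})
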