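test_that("fraction_intact normalises by the time-zero count", {
  f <- fraction_intact(data.frame(time_s = c(0, 30, 60),
                                  intact_count = c(200, 100, 50)))
  expect_equal(as.numeric(f), c(1, 0.5, 0.25))

  f <- fraction_intact(data.frame(time_s = c(0, 30, 60),
                                  intact_count = c(200, 200, 200)))
  expect_equal(as.numeric(f), c(1, 1, 1))

  # counting noise can push later fractions above 1; flagged, not an error
  f <- fraction_intact(data.frame(time_s = c(0, 30),
                                  intact_count = c(100, 110)))
  expect_identical(attr(f, "flagged_gt1"), 2L)

  expect_error(fraction_intact(data.frame(time_s = c(0, 30),
                                          intact_count = c(0, 10))),
               "no grains at t=0")
  expect_error(fraction_intact(data.frame(time_s = c(30, 0),
                                          intact_count = c(10, 20))),
               "strictly increasing")
})

test_that("noiseless exponential data is recovered to machine precision", {
  tt <- c(0, 30, 60, 120, 300, 600)
  fit <- fit_rupture(exp(-0.01 * tt), time_s = tt)
  expect_equal(fit$k, 0.01, tolerance = 1e-12)
  expect_lt(fit$rss, 1e-20)
  expect_length(fit$flags, 0)
})

test_that("a flat series yields k = 0 with the no-decay flag", {
  fit <- fit_rupture(c(1, 1, 1), time_s = c(0, 30, 60))
  expect_equal(fit$k, 0)
  expect_true("no_decay" %in% fit$flags)
  t95 <- time_to_rupture(fit, 0.95)
  expect_true(is.na(t95))
  expect_true(attr(t95, "unreachable"))
  expect_equal(as.numeric(time_to_rupture(fit, 0)), 0)
})

test_that("a single usable point is insufficient data", {
  expect_error(fit_rupture(c(1, 0, 0), time_s = c(0, 30, 60)),
               "insufficient data")
})

test_that("time_to_rupture inverts the exponential model in closed form", {
  tt <- c(0, 30, 60, 120, 300, 600)
  fit <- fit_rupture(exp(-0.0267465 * tt), time_s = tt)
  # t95 = log(20) / k, the rate observed for the fastest-rupturing conifer
  expect_equal(as.numeric(time_to_rupture(fit, 0.95)), 112.0,
               tolerance = 1e-4)
  expect_equal(as.numeric(time_to_rupture(fit, 0)), 0)

  # the t95/t33 ratio is a model constant, independent of k
  for (k in c(0.001, 0.0267465, 0.3)) {
    f <- fit_rupture(exp(-k * tt), time_s = tt)
    r <- as.numeric(time_to_rupture(f, 0.95) / time_to_rupture(f, 0.33))
    expect_equal(r, log(20) / log(1 / 0.67), tolerance = 1e-10)
  }
})

test_that("t_p increases in p and scales linearly with time units", {
  tt <- c(0, 30, 60, 120, 300, 600)
  fit <- fit_rupture(exp(-0.02 * tt), time_s = tt)
  ps <- c(0.1, 0.33, 0.67, 0.95, 0.999)
  tp <- as.numeric(time_to_rupture(fit, ps))
  expect_true(all(diff(tp) > 0))

  # stretch time by c: every t_p scales by c, optimal bead unchanged
  c_ <- 3
  fit2 <- fit_rupture(exp(-0.02 * tt), time_s = tt * c_)
  expect_equal(as.numeric(time_to_rupture(fit2, ps)), tp * c_,
               tolerance = 1e-8)
  t95 <- c(`0.5` = 700, `1.4` = 112, `2.8` = 300, `5.0` = 450)
  expect_identical(as.numeric(select_optimal_bead(t95)),
                   as.numeric(select_optimal_bead(t95 * c_)))
})

test_that("piecewise-linear inversion agrees with the exponential closed form on dense noiseless data", {
  tt <- seq(0, 900, by = 5)
  k <- 0.01
  fe <- fit_rupture(exp(-k * tt), time_s = tt)
  fp <- fit_rupture(exp(-k * tt), time_s = tt, model = "piecewise_linear")
  for (p in c(0.33, 0.67, 0.95)) {
    expect_equal(as.numeric(time_to_rupture(fp, p)),
                 as.numeric(time_to_rupture(fe, p)), tolerance = 0.01)
  }
  # beyond the observed range the last segment extrapolates, never NA here
  expect_false(is.na(time_to_rupture(fp, 0.9999)))
})

test_that("piecewise-linear fits keep zero-count points and flag flat series", {
  fp <- fit_rupture(c(1, 0.4, 0), time_s = c(0, 30, 60),
                    model = "piecewise_linear")
  expect_equal(as.numeric(time_to_rupture(fp, 0.95)),
               30 + (0.4 - 0.05) / 0.4 * 30)
  flat <- fit_rupture(c(1, 1, 1), time_s = c(0, 30, 60),
                      model = "piecewise_linear")
  expect_true("no_decay" %in% flat$flags)
  expect_true(is.na(time_to_rupture(flat, 0.5)))
})

test_that("optimal bead selection minimises t95 with deterministic tie-breaks", {
  expect_equal(as.numeric(select_optimal_bead(
    c(`0.5` = 700, `1.4` = 112, `2.8` = 300, `5.0` = 450))), 1.4)
  expect_equal(as.numeric(select_optimal_bead(c(`2.8` = 211))), 2.8)
  # ties go to the smaller bead (gentler processing)
  expect_equal(as.numeric(select_optimal_bead(c(`2.8` = 100, `1.4` = 100))),
               1.4)
  # unreachable candidates rank last but do not block selection
  expect_equal(as.numeric(select_optimal_bead(c(`0.5` = NA, `2.8` = 300))),
               2.8)
  expect_error(select_optimal_bead(c(`0.5` = NA_real_, `2.8` = NA_real_)),
               "no effective bead size")
})

test_that("t95 summaries use the sample SD and max-minus-min range", {
  expect_equal(summarize_t95(c(100, 100, 100)),
               c(mean = 100, sd = 0, range = 0))
  s <- summarize_t95(c(66, 660))
  expect_equal(s[["mean"]], 363)
  expect_equal(s[["range"]], 594)
  expect_error(summarize_t95(123), "at least 2")
})

test_that("seeded Poisson simulations recover the decay rate", {
  set.seed(2024)
  k_true <- 0.02
  khat <- replicate(200, {
    tr <- simulate_grinding_counts(k = k_true, baseline = 200)
    fit_rupture(tr)$k
  })
  expect_lt(abs(stats::median(khat) - k_true) / k_true, 0.10)

  # bias shrinks as the baseline grain count grows
  bias_at <- vapply(c(50, 400, 5000), function(b) {
    kh <- replicate(120, fit_rupture(simulate_grinding_counts(k = 0.02,
                                                              baseline = b))$k)
    abs(mean(kh) - 0.02)
  }, numeric(1))
  expect_lt(bias_at[3], bias_at[1])
  expect_lt(bias_at[3] / 0.02, 0.02)
})

test_that("fit_kinetics_table fits every species x bead series and pools replicates", {
  set.seed(7)
  g <- rbind(simulate_grinding_counts(0.02, species_code = "A", bead_size_mm = 1.4),
             simulate_grinding_counts(0.02, species_code = "A", bead_size_mm = 1.4,
                                      replicate_id = 2L),
             simulate_grinding_counts(0.005, species_code = "A", bead_size_mm = 5.0),
             simulate_grinding_counts(0.05, species_code = "B", bead_size_mm = 1.4))
  kin <- fit_kinetics_table(g)
  expect_identical(nrow(kin), 3L)
  expect_true(all(kin$t33 < kin$t67 & kin$t67 < kin$t95 &
                    kin$t95 < kin$t_complete))
  a14 <- kin[kin$species_code == "A" & kin$bead_size_mm == 1.4, ]
  expect_equal(a14$k, 0.02, tolerance = 0.25)
})

test_that("rupture_fit behaves like a fitted model object", {
  tt <- c(0, 30, 60, 120, 300, 600)
  set.seed(3)
  fit <- fit_rupture(simulate_grinding_counts(0.01, baseline = 500),
                     species_code = "AC", bead_size_mm = 1.4)
  expect_named(coef(fit), "k")
  expect_equal(predict(fit, 0), 1)
  expect_equal(length(residuals(fit)), length(tt))
  expect_lt(mean(abs(residuals(fit))), 0.1)
  expect_output(print(fit), "decay rate")
  expect_output(print(summary(fit)), "half-life")
  sims <- simulate(fit, nsim = 3, seed = 1, baseline = 300)
  expect_identical(dim(sims), c(6L, 3L))
})
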