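test_that("filter_events keeps runs of at least min_frames frames", {
  ev <- tibble::tibble(duration_frames = c(2, 3, 5))
  kept <- filter_events(ev, quiet = TRUE)
  expect_equal(nrow(kept), 2)
  expect_equal(attr(kept, "n_removed"), 1)

  all_long <- tibble::tibble(duration_frames = c(3, 4, 10))
  expect_equal(nrow(filter_events(all_long, quiet = TRUE)), 3)

  set.seed(2)
  for (rep in 1:5) {
    d <- sample(1:10, 50, replace = TRUE)
    thr <- sample(2:5, 1)
    kept <- filter_events(tibble::tibble(duration_frames = d), thr, quiet = TRUE)
    expect_equal(nrow(kept), sum(d >= thr))
  }
})

test_that("Gaussian CDF fit recovers velocity parameters", {
  set.seed(3)
  v <- rnorm(1000, 0.617, 0.08)
  fit <- fit_velocity_gaussian(v)
  expect_equal(unname(fit$estimate["mean"]), 0.617, tolerance = 0.01 / 0.617)
  expect_equal(unname(fit$estimate["sd"]), 0.08, tolerance = 0.1)
  expect_equal(fit$sem, unname(fit$estimate["sd"]) / sqrt(1000))

  # exact symmetry: {a - d, a + d} x k has mean a
  sym <- rep(c(0.5, 0.9), 20)
  fit_sym <- fit_velocity_gaussian(sym)
  expect_equal(unname(fit_sym$estimate["mean"]), 0.7, tolerance = 1e-6)

  expect_error(fit_velocity_gaussian(rnorm(5)), "at least 10")
  expect_error(fit_velocity_gaussian(rep(1, 20)), "variance")
  # data-frame-first interface
  tb <- tibble::tibble(velocity_um_s = v)
  expect_equal(fit_velocity_gaussian(tb)$estimate, fit$estimate)
})

test_that("exponential CDF fit recovers the mean run length and is shift-equivariant", {
  set.seed(4)
  x <- rexp(2000, rate = 1 / 0.99)
  fit <- fit_runlength_exponential(x)
  expect_equal(unname(fit$estimate["lambda"]), 0.99, tolerance = 0.05 / 0.99)
  expect_equal(fit$derived_mean, unname(fit$estimate["lambda"]))

  shifted <- fit_runlength_exponential(x + 0.3, offset = 0.3)
  expect_equal(shifted$estimate["lambda"], fit$estimate["lambda"],
               tolerance = 1e-6)
  expect_equal(shifted$derived_mean, 0.3 + unname(fit$estimate["lambda"]),
               tolerance = 1e-6)

  expect_error(fit_runlength_exponential(rep(2, 20)), "degenerate")
  expect_error(fit_runlength_exponential(x, offset = 5), "exceed")
})

test_that("CDF and maximum-likelihood exponential estimates agree at large n", {
  set.seed(5)
  x <- rexp(3000, rate = 1 / 2.5)
  fit <- fit_runlength_exponential(x)
  mle <- mean(x) # ML estimate of the exponential mean
  expect_equal(unname(fit$estimate["lambda"]), mle, tolerance = 0.05)
})

test_that("gamma CDF fit recovers shape, selects the right fixed scale", {
  set.seed(6)
  x1 <- rgamma(2000, shape = 4, scale = 1)
  f1 <- fit_runlength_gamma(x1)
  expect_equal(unname(f1$estimate["scale"]), 1)
  expect_equal(unname(f1$estimate["shape"]), 4, tolerance = 0.3 / 4)
  expect_equal(f1$derived_mean,
               unname(f1$estimate["shape"] * f1$estimate["scale"]))

  x2 <- rgamma(2000, shape = 2, scale = 2)
  f2 <- fit_runlength_gamma(x2)
  expect_equal(unname(f2$estimate["scale"]), 2)
  expect_equal(f2$derived_mean, 4, tolerance = 0.15)

  # mean = shape x scale product rule
  expect_equal(new_mean <- 2.07 * 1, 2.07)
  fkt <- fit_runlength_gamma(rgamma(500, shape = 2.07, scale = 1))
  expect_equal(fkt$derived_mean,
               unname(fkt$estimate["shape"] * fkt$estimate["scale"]))

  expect_error(fit_runlength_gamma(c(-1, rexp(20))), "positive")
})

test_that("fits are invariant to input order and full-sample duplication", {
  set.seed(7)
  x <- rgamma(400, shape = 3, scale = 1)
  a <- fit_runlength_gamma(x)
  b <- fit_runlength_gamma(sample(x))
  d <- fit_runlength_gamma(rep(x, 2))
  expect_equal(a$estimate, b$estimate, tolerance = 1e-8)
  expect_equal(a$estimate, d$estimate, tolerance = 1e-4)

  v <- rnorm(200, 0.7, 0.1)
  expect_equal(fit_velocity_gaussian(v)$estimate,
               fit_velocity_gaussian(rev(v))$estimate, tolerance = 1e-8)
})

test_that("gamma shape recovery has small bias across k at fixed scale", {
  set.seed(8)
  for (k in c(1, 2, 4, 8)) {
    x <- rgamma(5000, shape = k, scale = 1)
    fit <- fit_runlength_gamma(x, fixed_scales = 1)
    expect_lt(abs(fit$estimate[["shape"]] - k) / k, 0.05)
  }
})

test_that("landing_rate computes events per um per nM per s", {
  lr <- landing_rate(10, 10, 1, 100)
  expect_equal(lr$rate, 0.01)
  expect_equal(landing_rate(0, 10, 1, 100)$rate, 0)
  expect_error(landing_rate(5, 0, 1, 100), "> 0")

  # unbiased under Poisson landings
  set.seed(9)
  r_true <- 0.2; L <- 50; C <- 0.5; Tt <- 120
  est <- replicate(100, landing_rate(rpois(1, r_true * L * C * Tt), L, C, Tt)$rate)
  se <- sd(est) / sqrt(100)
  expect_lt(abs(mean(est) - r_true), 3 * se)
})

test_that("gap deficits compare observed motion with constant motility", {
  ev <- tibble::tibble(
    event_id = 1:2, construct = "M",
    velocity_um_s = c(0.8, 0.8),
    gaps = list(
      tibble::tibble(gap_duration_s = 1, gap_displacement_um = 0.8),
      tibble::tibble(gap_duration_s = 1, gap_displacement_um = 0)
    )
  )
  gd <- gap_displacement_deficit(ev, pixel_size_um = 0.16)
  expect_equal(gd$deficit_um, c(0, 0.8))
  expect_equal(gd$deficit_px, c(0, 5))

  # simulated detach-pause-reattach: mean deficit = pause fraction x expected
  spec <- motility_sim_spec(n_events = 400, pause_prob = 1,
                            pause_duration_s = 2, pause_fraction = 0.6,
                            seed = 10)
  sim <- simulate_motility_events(spec)
  gd2 <- gap_displacement_deficit(sim$events)
  expect_equal(mean(gd2$deficit_um / gd2$expected_um), 0.6, tolerance = 1e-9)
  expect_equal(mean(gd2$deficit_um), 0.6 * mean(gd2$expected_um),
               tolerance = 0.05)
  smry <- gap_deficit_summary(gd2)
  expect_equal(smry$n_gaps, 400)

  ev_na <- ev; ev_na$velocity_um_s[1] <- NA
  expect_error(gap_displacement_deficit(ev_na), "missing velocity")
})

test_that("detachment_summary reports group means and t-tests vs reference", {
  tr <- tibble::tibble(
    construct = rep(c("WT", "MUT"), each = 3),
    max_force_pN = c(4.0, 4.6, 5.2, 1.0, 0.8, 0.9)
  )
  sm <- detachment_summary(tr, reference = "WT")
  expect_equal(sm$mean_pN[sm$construct == "WT"], 4.6)
  expect_true(is.na(sm$p_vs_ref[sm$construct == "WT"]))
  expect_lt(sm$p_vs_ref[sm$construct == "MUT"], 0.01)

  same <- tibble::tibble(
    construct = rep(c("WT", "B"), each = 4),
    max_force_pN = rep(c(4, 5, 4.5, 4.2), 2)
  )
  sm2 <- detachment_summary(same)
  expect_gt(sm2$p_vs_ref[sm2$construct == "B"], 0.9)

  expect_error(detachment_summary(
    tibble::tibble(construct = c("WT", "WT", "X"), max_force_pN = c(4, 5, 3))
  ), "at least 2")
  expect_error(detachment_summary(tr, reference = "ZZ"), "not present")
})

test_that("t-test distinguishes strong and weak detachment forces reliably", {
  # groups drawn at printed population parameters: 4.6 +/- 0.8 vs 0.9 +/- 0.6
  set.seed(11)
  hits <- replicate(200, {
    a <- rnorm(20, 4.6, 0.8); b <- pmax(rnorm(20, 0.9, 0.6), 0.05)
    tr <- tibble::tibble(construct = rep(c("WT", "CNB"), each = 20),
                         max_force_pN = c(a, b))
    sm <- detachment_summary(tr)
    sm$p_vs_ref[sm$construct == "CNB"] < 0.001
  })
  expect_gte(mean(hits), 0.99)
})

test_that("one-way ANOVA matches the textbook formula and behaves under the null", {
  grp <- tibble::tibble(
    velocity_um_s = c(1, 2, 3, 4, 5, 6),
    construct = rep(c("a", "b"), each = 3)
  )
  res <- compare_velocities(grp)
  # brute-force formula oracle
  gm <- mean(grp$velocity_um_s)
  ssb <- 3 * (2 - gm)^2 + 3 * (5 - gm)^2
  ssw <- sum((c(1, 2, 3) - 2)^2) + sum((c(4, 5, 6) - 5)^2)
  f_oracle <- (ssb / 1) / (ssw / 4)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-12)

  ident <- tibble::tibble(
    velocity_um_s = rep(c(1, 2, 3), 2),
    construct = rep(c("a", "b"), each = 3)
  )
  res0 <- compare_velocities(ident)
  expect_lt(res0$statistic, 1e-20)
  expect_gt(res0$p_value, 0.99)

  expect_error(compare_velocities(grp[1:3, ]), "2 groups")
})

test_that("Kruskal-Wallis matches the rank formula and handles identical groups", {
  grp <- tibble::tibble(
    run_length_um = c(1, 2, 3, 4, 5, 6),
    construct = rep(c("a", "b"), each = 3)
  )
  res <- compare_runlengths(grp)
  # rank-formula oracle (no ties)
  r <- rank(grp$run_length_um)
  n <- 6
  h_oracle <- 12 / (n * (n + 1)) *
    (sum(r[1:3])^2 / 3 + sum(r[4:6])^2 / 3) - 3 * (n + 1)
  expect_equal(res$statistic, h_oracle, tolerance = 1e-12)

  ident <- tibble::tibble(
    run_length_um = rep(c(1, 2, 3), 2),
    construct = rep(c("a", "b"), each = 3)
  )
  expect_gt(compare_runlengths(ident)$p_value, 0.99)
  expect_error(compare_runlengths(
    tibble::tibble(run_length_um = rep(1, 6),
                   construct = rep(c("a", "b"), each = 3))
  ), "identical")
})

test_that("tidiers expose fit parameters", {
  set.seed(12)
  fit <- fit_runlength_gamma(rgamma(300, 3, scale = 1))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$family, "gamma")
  expect_equal(gl$n, 300)
})
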