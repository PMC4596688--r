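test_that("bleach ratio is the late/early window mean ratio", {
  t <- seq(0, 10, by = 0.001)
  expect_equal(bleach_ratio(t, rep(3, length(t)), c(0, 1), c(9, 10)), 1)
  v <- ifelse(t < 5, 2, 1)
  expect_equal(bleach_ratio(t, v, c(0, 1), c(9, 10)), 0.5)
  # exponential decay: window means approach the analytic integrals
  analytic <- (exp(-9) - exp(-10)) / (1 - exp(-1))   # ratio of window integrals
  expect_equal(bleach_ratio(t, exp(-t), c(0, 1), c(9, 10)), analytic,
               tolerance = 1e-3)
  expect_error(bleach_ratio(t, exp(-t), c(0, 2), c(1, 3)), "disjoint")
  expect_error(bleach_ratio(t, exp(-t), c(-2, -1), c(9, 10)), "no trace")
})

test_that("direct-binding fraction matches limits and a bisection oracle", {
  expect_equal(fraction_bound_direct(0, 20e-9, 50e-9), 0)
  # half saturation in the no-depletion limit
  expect_equal(fraction_bound_direct(50e-9, 1e-15, 50e-9), 0.5,
               tolerance = 1e-6)
  f <- fraction_bound_direct(150e-9, 20e-9, 50e-9)
  R <- oracle_free_receptor(150e-9, 20e-9, 0, 50e-9, 1)
  expect_equal(f, R / (50e-9 + R), tolerance = 1e-9)
  # numerically stable at extreme receptor excess
  f_hi <- fraction_bound_direct(1e-2, 1e-9, 1e-9)
  expect_true(f_hi > 1 - 1e-6 && f_hi <= 1)
  expect_error(fraction_bound_direct(1e-9, 0, 1e-9), "probe")
})

test_that("the competition solver satisfies mass balance and its limits", {
  set.seed(12)
  n <- 2000
  Rt <- 10^runif(n, -9, -4); Pt <- 10^runif(n, -9, -5)
  Ct <- 10^runif(n, -9, -4); Kp <- 10^runif(n, -9, -5)
  Kc <- 10^runif(n, -9, -5)
  R <- free_receptor_competition(Rt, Pt, Ct, Kp, Kc)
  RP <- Pt * R / (Kp + R)
  RC <- Ct * R / (Kc + R)
  P <- Pt - RP
  C <- Ct - RC
  expect_lt(max(abs(R + RP + RC - Rt) / Rt), 1e-6)     # receptor balance
  expect_lt(max(abs(RP - R * P / Kp) / Pt), 1e-6)      # probe mass action
  expect_lt(max(abs(RC - R * C / Kc) / Ct), 1e-6)      # competitor mass action

  # zero competitor degenerates to the direct quadratic
  R0 <- free_receptor_competition(150e-9, 20e-9, 0, 50e-9, 590e-9)
  f0 <- R0 / (50e-9 + R0)
  bound <- fraction_bound_direct(150e-9, 20e-9, 50e-9)
  expect_equal(f0, bound, tolerance = 1e-10)

  # saturating competitor strips the probe
  Rinf <- free_receptor_competition(150e-9, 20e-9, 1, 50e-9, 590e-9)
  expect_lt(Rinf / (50e-9 + Rinf), 1e-4)

  # agreement with an independent bisection oracle on random draws
  set.seed(3)
  for (i in 1:10) {
    Rt <- 10^runif(1, -8, -5); Pt <- 10^runif(1, -9, -6)
    Ct <- 10^runif(1, -8, -4); Kp <- 10^runif(1, -9, -6)
    Kc <- 10^runif(1, -9, -5)
    expect_equal(free_receptor_competition(Rt, Pt, Ct, Kp, Kc),
                 oracle_free_receptor(Rt, Pt, Ct, Kp, Kc),
                 tolerance = 1e-8)
  }
})

test_that("predicted signals are monotone in the titrant", {
  params <- binding_params(50e-9, 590e-9)
  d <- predict_signal(params, direct_design())
  expect_true(all(diff(d) > 0))     # titrant descends, signal rises to s_free
  cmp <- predict_signal(params, competition_design())
  expect_true(all(diff(cmp) < 0))   # less competitor, more bound probe
})

test_that("noise-free titrations are recovered essentially exactly", {
  truth <- binding_params(kd_probe = 50e-9, kd_competitor = 590e-9)
  d <- simulate_titration(truth, direct_design(), 0, series_id = "d1")
  cc <- simulate_titration(truth, competition_design(), 0, series_id = "c1")
  fit <- fit_titrations(rbind(d, cc), ci = FALSE)
  expect_lt(abs(fit$estimates$kd_probe / 50e-9 - 1), 1e-3)
  expect_lt(abs(fit$estimates$kd_competitor / 590e-9 - 1), 1e-3)
  ep <- fit$estimates$endpoints
  expect_equal(unname(ep[1]), truth$s_free, tolerance = 1e-4)
  expect_equal(unname(ep[2]), truth$s_bound, tolerance = 1e-4)

  # direct-only fits work too
  fit_d <- fit_titrations(d, ci = FALSE)
  expect_lt(abs(fit_d$estimates$kd_probe / 50e-9 - 1), 1e-3)
  expect_true(is.na(fit_d$estimates$kd_competitor))

  # flat signals are unidentifiable
  flat <- d
  flat$signal <- 0.7
  expect_error(fit_titrations(flat), "zero variance")
})

test_that("titration validation rejects malformed series", {
  truth <- binding_params(50e-9, 590e-9)
  d <- simulate_titration(truth, direct_design(), 0, series_id = "d1")
  short <- d[1:3, ]
  expect_error(fit_titrations(short), "fewer than 5")
  shuffled <- d[c(2, 1, 3:16), ]
  expect_error(fit_titrations(shuffled), "strictly ordered")
  comp_only <- simulate_titration(truth, competition_design(), 0)
  expect_error(fit_titrations(comp_only), "direct")
})

test_that("profile intervals match the closed form on a quadratic error surface", {
  ssr_min <- 2.5
  dof <- 20
  theta0 <- 1e-7
  curv <- 4.0                       # SSR = ssr_min + curv * log(theta/theta0)^2
  pfun <- function(theta) ssr_min + curv * log(theta / theta0)^2
  fcrit <- stats::qf(0.683, 1, dof)
  threshold <- ssr_min * (1 + fcrit / dof)
  ivl <- nescan:::profile_interval(pfun, theta0, threshold)
  half <- sqrt(ssr_min * fcrit / dof / curv)
  expect_equal(log(ivl[1] / theta0), -half, tolerance = 1e-3)
  expect_equal(log(ivl[2] / theta0), half, tolerance = 1e-3)
  # a surface that never crosses the threshold is flagged open
  flat <- nescan:::profile_interval(function(x) ssr_min, theta0, threshold,
                                    lower_limit = theta0 / 100,
                                    upper_limit = theta0 * 100)
  expect_true(all(is.na(flat)))
  expect_true(all(attr(flat, "open")))
})

test_that("error-surface confidence intervals bracket the estimate and collapse at level 0", {
  set.seed(41)
  truth <- binding_params(50e-9, 590e-9)
  d <- simulate_titration(truth, direct_design(), 0.02, series_id = "d1")
  cc <- simulate_titration(truth, competition_design(), 0.02,
                           series_id = "c1")
  fit <- fit_titrations(rbind(d, cc), ci = FALSE)
  ci <- ci_error_surface(fit, "kd_competitor")
  expect_lt(ci[1], fit$estimates$kd_competitor)
  expect_gt(ci[2], fit$estimates$kd_competitor)
  ci0 <- ci_error_surface(fit, "kd_competitor", level = 0)
  expect_equal(unname(ci0[1]), fit$estimates$kd_competitor)
  expect_equal(unname(ci0[2]), fit$estimates$kd_competitor)
  expect_error(ci_error_surface(fit, "s_free"), "s_free")
})
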