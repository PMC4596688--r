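#' @title Competition differential-bleaching binding model
#' @description The assay readout is a bleach ratio: the mean
#'   fluorescence in a window late in the bleaching phase divided by the
#'   mean just after bleaching starts. Free and receptor-bound probe
#'   bleach at different specific rates, so the ratio is a two-state
#'   observable linear in the bound-probe fraction. Direct titrations
#'   (receptor titrated into fluorescent probe) calibrate the probe
#'   dissociation constant and the signal endpoints; competition
#'   titrations (unlabelled competitor titrated into probe + receptor)
#'   measure the competitor dissociation constant through the exact
#'   three-species equilibrium. All concentrations are molar and refer
#'   to final (post-mixing) assay concentrations.
#' @name binding
NULL

#' Bleach ratio from a timed fluorescence trace
#'
#' @param times Numeric vector of time points.
#' @param values Fluorescence readings at `times`.
#' @param early_window Length-2 numeric, inclusive time window just after
#'   the beginning of bleaching.
#' @param late_window Length-2 numeric window later in the trace; must be
#'   disjoint from and after the early window.
#' @return `mean(values in late) / mean(values in early)`.
#' @export
bleach_ratio <- function(times, values, early_window, late_window) {
  stopifnot(length(times) == length(values),
            length(early_window) == 2L, length(late_window) == 2L)
  if (early_window[2] >= late_window[1]) {
    stop("early window must precede and be disjoint from the late window")
  }
  ei <- times >= early_window[1] & times <= early_window[2]
  li <- times >= late_window[1] & times <= late_window[2]
  if (!any(ei)) stop("early window contains no trace points")
  if (!any(li)) stop("late window contains no trace points")
  mean(values[li]) / mean(values[ei])
}

#' Bound-probe fraction in a 1:1 direct titration
#'
#' Exact single-site depletion solution of
#' `R + P <-> RP` with totals `C` (receptor) and `P` (probe):
#' `f = ((C+P+K) - sqrt((C+P+K)^2 - 4CP)) / (2P)`, evaluated in the
#' numerically stable form `2C / (S + sqrt(S^2 - 4CP))` so that the
#' large-receptor limit (`C >> P`) does not lose precision to
#' cancellation.
#'
#' @param receptor_total Total receptor concentration(s), molar.
#' @param probe_total Total probe concentration(s), molar (> 0).
#' @param kd Probe dissociation constant, molar (> 0).
#' @return Bound fraction(s) in `[0, 1]`.
#' @export
fraction_bound_direct <- function(receptor_total, probe_total, kd) {
  if (any(probe_total <= 0)) {
    stop("probe_total must be > 0 (no probe: bound fraction undefined)")
  }
  if (any(kd <= 0)) stop("kd must be > 0")
  if (any(receptor_total < 0)) stop("receptor_total must be >= 0")
  s <- receptor_total + probe_total + kd
  disc <- s^2 - 4 * receptor_total * probe_total
  f <- 2 * receptor_total / (s + sqrt(pmax(disc, 0)))
  pmin(pmax(f, 0), 1)
}

#' Free receptor concentration in a three-species competition
#'
#' Probe and competitor bind the same receptor site mutually
#' exclusively. The free receptor concentration `R` is the unique root
#' in `[0, receptor_total]` of the mass-balance cubic
#' `R (1 + P_t/(K_p + R) + C_t/(K_c + R)) = R_t`. The root is evaluated
#' by the trigonometric closed form of the cubic, polished with Newton
#' steps, with a bisection fallback; the returned solution satisfies all
#' conservation equations to better than 1e-6 relative (an error is
#' raised otherwise, echoing the inputs).
#'
#' With `competitor_total = 0` the exact two-species (direct quadratic)
#' solution is returned.
#'
#' @param receptor_total,probe_total,competitor_total Total
#'   concentrations, molar (vectors recycled to a common length).
#' @param kd_probe,kd_competitor Dissociation constants, molar (> 0).
#' @return Free receptor concentration(s), molar. The bound-probe
#'   fraction follows as `R / (kd_probe + R)`.
#' @export
free_receptor_competition <- function(receptor_total, probe_total,
                                      competitor_total, kd_probe,
                                      kd_competitor) {
  n <- max(length(receptor_total), length(probe_total),
           length(competitor_total), length(kd_probe),
           length(kd_competitor))
  Rt <- rep_len(as.numeric(receptor_total), n)
  Pt <- rep_len(as.numeric(probe_total), n)
  Ct <- rep_len(as.numeric(competitor_total), n)
  Kp <- rep_len(as.numeric(kd_probe), n)
  Kc <- rep_len(as.numeric(kd_competitor), n)
  if (any(Kp <= 0) || any(Kc <= 0)) stop("dissociation constants must be > 0")
  if (any(Rt < 0) || any(Pt < 0) || any(Ct < 0)) {
    stop("total concentrations must be >= 0")
  }
  R <- numeric(n)
  zero <- Rt == 0
  # two-species exact quadratic when there is no competitor
  direct <- !zero & Ct == 0
  if (any(direct)) {
    a <- Kp[direct] + Pt[direct] - Rt[direct]
    sq <- sqrt(a^2 + 4 * Kp[direct] * Rt[direct])
    R[direct] <- ifelse(a > 0, 2 * Kp[direct] * Rt[direct] / (a + sq),
                        (sq - a) / 2)
  }
  gen <- !zero & Ct > 0
  if (any(gen)) {
    R[gen] <- solve_competition_cubic(Rt[gen], Pt[gen], Ct[gen],
                                      Kp[gen], Kc[gen])
  }
  # verify receptor conservation (probe/competitor balances are implied
  # by the isotherm form used below but are checked in the test suite)
  resid <- mass_balance_residual(R, Rt, Pt, Ct, Kp, Kc)
  bad <- !zero & resid > 1e-6
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "no positive equilibrium root within tolerance (residual %.3g) for Rt=%g, Pt=%g, Ct=%g, Kp=%g, Kc=%g",
      resid[i], Rt[i], Pt[i], Ct[i], Kp[i], Kc[i]))
  }
  R
}

# relative receptor-conservation residual at free-receptor value R
mass_balance_residual <- function(R, Rt, Pt, Ct, Kp, Kc) {
  g <- R * (1 + Pt / (Kp + R) + Ct / (Kc + R)) - Rt
  ifelse(Rt > 0, abs(g) / Rt, abs(g))
}

solve_competition_cubic <- function(Rt, Pt, Ct, Kp, Kc) {
  a <- Kp + Kc + Pt + Ct - Rt
  b <- Kc * (Pt - Rt) + Kp * (Ct - Rt) + Kp * Kc
  cc <- -Kp * Kc * Rt
  q <- a^2 - 3 * b
  R <- rep(NA_real_, length(Rt))
  okq <- q > 0
  if (any(okq)) {
    arg <- (-2 * a[okq]^3 + 9 * a[okq] * b[okq] - 27 * cc[okq]) /
      (2 * sqrt(q[okq]^3))
    theta <- acos(pmin(1, pmax(-1, arg)))
    R[okq] <- -a[okq] / 3 + (2 / 3) * sqrt(q[okq]) * cos(theta / 3)
  }
  # Newton polish on g(R) = R (1 + Pt/(Kp+R) + Ct/(Kc+R)) - Rt
  for (it in 1:4) {
    ok <- is.finite(R) & R > 0
    if (!any(ok)) break
    g <- R[ok] * (1 + Pt[ok] / (Kp[ok] + R[ok]) + Ct[ok] / (Kc[ok] + R[ok])) -
      Rt[ok]
    dg <- 1 + Pt[ok] * Kp[ok] / (Kp[ok] + R[ok])^2 +
      Ct[ok] * Kc[ok] / (Kc[ok] + R[ok])^2
    R[ok] <- pmin(pmax(R[ok] - g / dg, 0), Rt[ok])
  }
  resid <- mass_balance_residual(R, Rt, Pt, Ct, Kp, Kc)
  bad <- !is.finite(R) | R < 0 | R > Rt | resid > 1e-9
  if (any(bad)) {
    # bisection fallback: g is strictly increasing, g(0) < 0 <= g(Rt)
    lo <- rep(0, sum(bad))
    hi <- Rt[bad]
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      g <- mid * (1 + Pt[bad] / (Kp[bad] + mid) + Ct[bad] / (Kc[bad] + mid)) -
        Rt[bad]
      up <- g > 0
      hi[up] <- mid[up]
      lo[!up] <- mid[!up]
    }
    R[bad] <- (lo + hi) / 2
  }
  R
}

#' Construct a validated binding-parameter set
#'
#' @param kd_probe Probe (FITC-labelled NES) dissociation constant, molar.
#' @param kd_competitor Competitor dissociation constant, molar (`NA`
#'   allowed when no competition series is modelled).
#' @param s_free,s_bound Bleach-ratio endpoints of the free and bound
#'   probe (must differ).
#' @return List of class `binding_params`.
#' @export
binding_params <- function(kd_probe, kd_competitor = NA_real_,
                           s_free = 0.85, s_bound = 0.55) {
  if (!is.finite(kd_probe) || kd_probe <= 0) stop("kd_probe must be > 0")
  if (!is.na(kd_competitor) &&
      (!is.finite(kd_competitor) || kd_competitor <= 0)) {
    stop("kd_competitor must be > 0 (or NA)")
  }
  if (!is.finite(s_free) || !is.finite(s_bound) || s_free == s_bound) {
    stop("signal endpoints must be finite and distinct")
  }
  structure(list(kd_probe = kd_probe, kd_competitor = kd_competitor,
                 s_free = s_free, s_bound = s_bound),
            class = "binding_params")
}

# Bound-probe fraction for each titration row.
model_fraction <- function(data, kd_probe, kd_competitor = NA_real_) {
  f <- numeric(nrow(data))
  d <- data$mode == "direct"
  if (any(d)) {
    f[d] <- fraction_bound_direct(data$titrant_total[d],
                                  data$probe_total[d], kd_probe)
  }
  if (any(!d)) {
    if (is.na(kd_competitor)) {
      stop("competition series present but kd_competitor is NA")
    }
    R <- free_receptor_competition(data$receptor_total[!d],
                                   data$probe_total[!d],
                                   data$titrant_total[!d],
                                   kd_probe, kd_competitor)
    f[!d] <- R / (kd_probe + R)
  }
  f
}

#' Predict bleach-ratio signals for a titration table
#'
#' @param params A [binding_params()] object.
#' @param data Titration table with columns `mode` (`direct` /
#'   `competition`), `probe_total`, `receptor_total` (competition rows)
#'   and `titrant_total` (molar; the titrant is the receptor in direct
#'   mode and the competitor in competition mode).
#' @return Numeric vector of predicted signals,
#'   `s_free + (s_bound - s_free) * f_bound`.
#' @export
predict_signal <- function(params, data) {
  stopifnot(inherits(params, "binding_params"))
  f <- model_fraction(data, params$kd_probe, params$kd_competitor)
  params$s_free + (params$s_bound - params$s_free) * f
}

# ---- fitting -----------------------------------------------------------

validate_titrations <- function(data) {
  need <- c("series_id", "mode", "probe_total", "titrant_total", "signal")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop(sprintf("titration table: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  }
  if (!all(data$mode %in% c("direct", "competition"))) {
    stop("titration mode must be 'direct' or 'competition'")
  }
  if (!("receptor_total" %in% names(data))) data$receptor_total <- NA_real_
  comp <- data$mode == "competition"
  if (any(comp & (is.na(data$receptor_total) | data$receptor_total < 0))) {
    stop("competition rows need a non-negative receptor_total")
  }
  if (any(data$titrant_total < 0) || any(data$probe_total <= 0)) {
    stop("concentrations must be non-negative (probe_total > 0)")
  }
  if (any(!is.finite(data$signal) | data$signal <= 0)) {
    stop("signals must be finite and > 0")
  }
  for (sid in unique(data$series_id)) {
    tt <- data$titrant_total[data$series_id == sid]
    if (length(tt) < 5L) {
      stop(sprintf("series '%s' has fewer than 5 points", sid))
    }
    d <- diff(tt)
    if (!(all(d > 0) || all(d < 0))) {
      stop(sprintf("series '%s': titrant concentrations must be strictly ordered",
                   sid))
    }
  }
  data
}

# Endpoint design matrix: signal = s_free * (1 - f) + s_bound * f,
# shared across series or one endpoint pair per series.
endpoint_design <- function(f, series, share_endpoints) {
  if (share_endpoints) {
    cbind(s_free = 1 - f, s_bound = f)
  } else {
    lev <- unique(series)
    X <- matrix(0, length(f), 2L * length(lev))
    cn <- character(2L * length(lev))
    for (k in seq_along(lev)) {
      sel <- series == lev[k]
      X[sel, 2L * k - 1L] <- 1 - f[sel]
      X[sel, 2L * k] <- f[sel]
      cn[2L * k - 1L] <- paste0("s_free.", lev[k])
      cn[2L * k] <- paste0("s_bound.", lev[k])
    }
    colnames(X) <- cn
    X
  }
}

#' Fit dissociation constants to direct and competition titrations
#'
#' Unweighted least squares on bleach-ratio signals over all points
#' jointly. Direct series determine the probe dissociation constant and
#' the signal endpoints; competition series determine the competitor
#' dissociation constant. Dissociation constants are log-parameterised
#' and optimised by multistart Nelder-Mead (profile over a coarse log
#' grid seeds the starts); given the constants, the endpoints are the
#' exact linear least-squares solution.
#'
#' @param data Titration table (see [predict_signal()]; additionally a
#'   `series_id` column and, for validation, `replicate` if available).
#'   At least one direct series is required.
#' @param share_endpoints Share one (s_free, s_bound) pair across all
#'   series (default) or fit one pair per series.
#' @param n_starts Number of multistart seeds for each dissociation
#'   constant.
#' @param kd_range Log-uniform search range for the constants, molar.
#' @param ci Also compute 68.3% error-surface confidence intervals for
#'   the fitted dissociation constants (see [ci_error_surface()]).
#' @param ci_level Confidence level for `ci` (default 0.683).
#' @return Object of class `binding_fit`: estimates, `ssr`, `dof`,
#'   per-point fitted values and residuals, convergence diagnostics and
#'   (when requested) `ci68`.
#' @export
fit_titrations <- function(data, share_endpoints = TRUE, n_starts = 4,
                           kd_range = c(1e-10, 1e-4), ci = TRUE,
                           ci_level = 0.683) {
  data <- validate_titrations(as.data.frame(data))
  if (!any(data$mode == "direct")) {
    stop("at least one direct titration series is required")
  }
  dsig <- data$signal[data$mode == "direct"]
  if (stats::sd(dsig) < 1e-12 * max(abs(dsig))) {
    stop("direct titration signals have zero variance: endpoints and kd_probe are unidentifiable")
  }
  has_comp <- any(data$mode == "competition")
  lr <- log(kd_range)

  ssr_at <- function(logkdp, logkdc = NA_real_) {
    f <- tryCatch(model_fraction(data, exp(logkdp),
                                 if (is.na(logkdc)) NA_real_ else exp(logkdc)),
                  error = function(e) NULL)
    if (is.null(f)) return(list(ssr = Inf, coef = NULL, f = NULL))
    X <- endpoint_design(f, data$series_id, share_endpoints)
    fit <- stats::lm.fit(X, data$signal)
    list(ssr = sum(fit$residuals^2), coef = fit$coefficients, f = f)
  }

  # stage 1: probe kd from the direct series alone (grid + golden section)
  ddata <- data[data$mode == "direct", , drop = FALSE]
  dssr <- function(logkdp) {
    f <- fraction_bound_direct(ddata$titrant_total, ddata$probe_total,
                               exp(logkdp))
    X <- endpoint_design(f, ddata$series_id, share_endpoints)
    sum(stats::lm.fit(X, ddata$signal)$residuals^2)
  }
  grid <- seq(lr[1], lr[2], length.out = 40L)
  gv <- vapply(grid, dssr, numeric(1))
  k <- which.min(gv)
  bracket <- c(grid[max(1L, k - 1L)], grid[min(length(grid), k + 1L)])
  logkdp0 <- stats::optimize(dssr, bracket, tol = 1e-10)$minimum

  if (!has_comp) {
    best <- list(par = logkdp0, value = ssr_at(logkdp0)$ssr,
                 convergence = 0L)
    est_logkdc <- NA_real_
    est_logkdp <- logkdp0
  } else {
    cgrid <- seq(lr[1], lr[2], length.out = 25L)
    cv <- vapply(cgrid, function(lc) ssr_at(logkdp0, lc)$ssr, numeric(1))
    seeds <- cgrid[order(cv)][seq_len(min(n_starts, length(cgrid)))]
    runs <- lapply(seeds, function(s) {
      stats::optim(c(logkdp0, s),
                   function(p) ssr_at(p[1], p[2])$ssr,
                   method = "Nelder-Mead",
                   control = list(reltol = 1e-13, maxit = 2000L))
    })
    best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
    # restart once from the best point to escape simplex collapse
    best <- stats::optim(best$par, function(p) ssr_at(p[1], p[2])$ssr,
                         method = "Nelder-Mead",
                         control = list(reltol = 1e-13, maxit = 2000L))
    est_logkdp <- best$par[1]
    est_logkdc <- best$par[2]
  }
  sol <- ssr_at(est_logkdp, est_logkdc)
  if (!is.finite(sol$ssr)) {
    stop("fit did not converge: best objective is not finite")
  }
  npar <- (1L + as.integer(has_comp)) + length(sol$coef)
  dof <- nrow(data) - npar
  X <- endpoint_design(sol$f, data$series_id, share_endpoints)
  fitted <- as.numeric(X %*% sol$coef)

  profile_fun <- function(parameter, value) {
    lv <- log(value)
    if (parameter == "kd_probe") {
      if (!has_comp) return(ssr_at(lv)$ssr)
      stats::optimize(function(lc) ssr_at(lv, lc)$ssr,
                      c(est_logkdc - log(1e4), est_logkdc + log(1e4)),
                      tol = 1e-9)$objective
    } else if (parameter == "kd_competitor") {
      if (!has_comp) stop("no competition series: kd_competitor not fitted")
      stats::optimize(function(lp) ssr_at(lp, lv)$ssr,
                      c(est_logkdp - log(1e4), est_logkdp + log(1e4)),
                      tol = 1e-9)$objective
    } else {
      stop(sprintf("cannot profile parameter '%s' (only dissociation constants)",
                   parameter))
    }
  }

  fit <- structure(list(
    estimates = list(kd_probe = exp(est_logkdp),
                     kd_competitor = if (has_comp) exp(est_logkdc) else
                       NA_real_,
                     endpoints = sol$coef),
    ssr = sol$ssr, dof = dof, n = nrow(data),
    fitted = fitted, residuals = data$signal - fitted,
    data = data, share_endpoints = share_endpoints,
    convergence = if (is.null(best$convergence)) 0L else best$convergence,
    profile = profile_fun), class = "binding_fit")

  if (ci && dof >= 1L) {
    fit$ci68 <- list(kd_probe = ci_error_surface(fit, "kd_probe",
                                                 level = ci_level))
    if (has_comp) {
      fit$ci68$kd_competitor <- ci_error_surface(fit, "kd_competitor",
                                                 level = ci_level)
    }
  }
  fit
}

#' @export
print.binding_fit <- function(x, ...) {
  fmt_nm <- function(v) if (is.na(v)) "NA" else sprintf("%.3g nM", v * 1e9)
  cat(sprintf("<binding_fit> kd_probe = %s, kd_competitor = %s\n",
              fmt_nm(x$estimates$kd_probe),
              fmt_nm(x$estimates$kd_competitor)))
  cat(sprintf("  SSR = %.4g on %d dof (%d points)\n", x$ssr, x$dof, x$n))
  if (!is.null(x$ci68)) {
    for (nm in names(x$ci68)) {
      ci <- x$ci68[[nm]]
      cat(sprintf("  %s 68.3%% CI: [%s, %s]\n", nm,
                  fmt_nm(ci[1]), fmt_nm(ci[2])))
    }
  }
  invisible(x)
}

# Find where a profiled SSR crosses a threshold on each side of the
# estimate. pfun(theta) must equal ssr_min at theta = est. Returns
# c(low, high) with NA on a side whose bound was not crossed inside
# [lower_limit, upper_limit]; attribute "open" flags such sides.
profile_interval <- function(pfun, est, threshold,
                             lower_limit = est * 1e-6,
                             upper_limit = est * 1e6,
                             step = 1.3, tol = 1e-4) {
  walk <- function(direction) {
    fac <- if (direction > 0) step else 1 / step
    limit <- if (direction > 0) upper_limit else lower_limit
    inner <- est
    theta <- est * fac
    repeat {
      hit_limit <- (direction > 0 && theta >= limit) ||
        (direction < 0 && theta <= limit)
      if (hit_limit) theta <- limit
      v <- pfun(theta)
      if (is.finite(v) && v > threshold) break
      if (hit_limit) return(c(NA_real_, TRUE))
      inner <- theta
      theta <- theta * fac
    }
    lo <- min(inner, theta)
    hi <- max(inner, theta)
    while (hi / lo > 1 + tol) {
      mid <- sqrt(lo * hi)
      v <- pfun(mid)
      crossed <- is.finite(v) && v > threshold
      if (direction > 0) {
        if (crossed) hi <- mid else lo <- mid
      } else {
        if (crossed) lo <- mid else hi <- mid
      }
    }
    c(sqrt(lo * hi), FALSE)
  }
  lo <- walk(-1)
  hi <- walk(+1)
  out <- c(lo[1], hi[1])
  attr(out, "open") <- c(lower = as.logical(lo[2]), upper = as.logical(hi[2]))
  out
}

#' Error-surface (F-statistic) confidence interval for a fitted constant
#'
#' Scans the named dissociation constant on a log grid away from its
#' estimate, re-optimising all other parameters at each value (profile
#' SSR), and reports the interval where
#' `SSR(theta) <= SSR_min * (1 + F_crit(1, dof, level) / dof)`.
#' Endpoints are refined by bisection to three significant digits. A
#' side whose threshold is not crossed within the scan range is reported
#' as `NA` and flagged open (attribute `"open"`).
#'
#' @param fit A converged [fit_titrations()] object with `dof >= 1`.
#' @param parameter `"kd_probe"` or `"kd_competitor"`.
#' @param level Confidence level (default 0.683, i.e. 68.3%).
#' @return Length-2 numeric `(low, high)` in molar units, with
#'   attributes `level` and `open`.
#' @export
ci_error_surface <- function(fit, parameter, level = 0.683) {
  stopifnot(inherits(fit, "binding_fit"))
  if (fit$dof < 1L) stop("need dof >= 1 for an F-statistic interval")
  est <- fit$estimates[[parameter]]
  if (is.null(est) || is.na(est)) {
    stop(sprintf("parameter '%s' was not fitted", parameter))
  }
  fcrit <- stats::qf(level, 1, fit$dof)
  if (fcrit <= 0) {
    out <- c(est, est)
    attr(out, "open") <- c(lower = FALSE, upper = FALSE)
    attr(out, "level") <- level
    return(out)
  }
  threshold <- fit$ssr * (1 + fcrit / fit$dof)
  pfun <- function(theta) fit$profile(parameter, theta)
  out <- profile_interval(pfun, est, threshold)
  attr(out, "level") <- level
  out
}

# ---- titration table I/O ----------------------------------------------

#' Read a titration table (CSV or TSV)
#'
#' Expected columns: `series_id`, `mode`, `replicate` (optional),
#' `probe_total_M`, `receptor_total_M`, `titrant_total_M` and either
#' `signal` or the raw window means `pre_mean`/`post_mean` (in which
#' case the bleach ratio `post_mean / pre_mean` is derived). Plain
#' `probe_total` etc. (already molar) are also accepted.
#'
#' @param path Input file; comma-separated for `.csv`, else tab.
#' @return Validated titration data frame in internal (molar) columns.
#' @export
read_titrations <- function(path) {
  if (!file.exists(path)) stop(sprintf("titration file not found: %s", path))
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  ren <- c(probe_total_M = "probe_total", receptor_total_M = "receptor_total",
           titrant_total_M = "titrant_total")
  for (nm in names(ren)) {
    if (nm %in% names(df) && !(ren[[nm]] %in% names(df))) {
      names(df)[names(df) == nm] <- ren[[nm]]
    }
  }
  if (!("signal" %in% names(df))) {
    if (all(c("pre_mean", "post_mean") %in% names(df))) {
      df$signal <- df$post_mean / df$pre_mean
    } else {
      stop(sprintf("titration table '%s': need a 'signal' column or pre_mean/post_mean",
                   path))
    }
  }
  validate_titrations(df)
}

#' Write a titration table as CSV
#' @param data Titration data frame (internal molar columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titrations <- function(data, path) {
  out <- data.frame(series_id = data$series_id, mode = data$mode,
                    replicate = if ("replicate" %in% names(data))
                      data$replicate else 1L,
                    probe_total_M = data$probe_total,
                    receptor_total_M = data$receptor_total,
                    titrant_total_M = data$titrant_total,
                    signal = data$signal)
  atomic_write(path, function(tmp) {
    utils::write.csv(out, tmp, row.names = FALSE, quote = FALSE)
  })
  invisible(path)
}

#' Serialize a binding fit as JSON
#' @param fit A `binding_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    estimates = list(
      kd_probe_M = fit$estimates$kd_probe,
      kd_competitor_M = fit$estimates$kd_competitor,
      endpoints = as.list(fit$estimates$endpoints)),
    ssr = fit$ssr, dof = fit$dof, n_points = fit$n,
    convergence = fit$convergence)
  if (!is.null(fit$ci68)) {
    payload$ci68 <- lapply(fit$ci68, function(ci) {
      list(low = ci[1], high = ci[2],
           open = as.list(attr(ci, "open")))
    })
  }
  atomic_write(path, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  })
  invisible(path)
}
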