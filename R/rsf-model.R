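# Use-availability resource selection over departure time: for every used
# departure time, available times are drawn from the preceding 96 h, the
# design is annotated with environmental covariates, and a weighted
# binomial GAM (logit link, penalized cubic spline smooths for the solar
# and tidal clocks) is fitted. Available rows get large weights so the
# logistic fit approximates the point-process likelihood of the RSF
# (the infinitely-weighted logistic regression device).

#' Sample available times before a departure
#'
#' Draws `n` distinct times uniformly without replacement from the
#' 10-min grid covering the `window` hours preceding the used time
#' (excluding the used time itself).
#'
#' @param t_used POSIXct used (departure) time.
#' @param n Number of available times (default 30).
#' @param window Hours, default 96.
#' @param grid_min Grid cadence in minutes, default 10.
#' @return POSIXct vector of length `n`.
#' @export
sample_available <- function(t_used, n = 30, window = 96, grid_min = 10) {
  t_used <- as_utc(t_used)
  grid <- t_used - seq(grid_min * 60, window * 3600, by = grid_min * 60)
  if (n > length(grid)) {
    abort("more available points requested than grid cells",
          class = "knotflight_sampling_error")
  }
  sort(grid[sample.int(length(grid), n)])
}

#' Build the used/available design
#'
#' One used row (response 1, weight 1) and `n_avail` available rows
#' (response 0, weight `avail_weight`) per departure event, annotated
#' with the departure covariates.
#'
#' @param events Tibble with `tag_id` and `departure_time` (e.g. the
#'   departed rows of [classify_departures()]).
#' @param env An [env_bundle()] covering all times.
#' @param n_avail Available times per event (default 30).
#' @param window Availability window in hours (default 96).
#' @param avail_weight Weight of available rows (default 1000).
#' @param track_bearing Bearing for wind assistance (default: bundle goal
#'   bearing).
#' @param seed Optional integer for the availability sampling.
#' @return Tibble: `event_id`, `t`, `response`, `weight`, covariates,
#'   `year`.
#' @export
build_rsf_design <- function(events, env, n_avail = 30, window = 96,
                             avail_weight = 1000, track_bearing = NULL,
                             seed = NULL) {
  if (!all(c("tag_id", "departure_time") %in% names(events))) {
    abort("events need tag_id and departure_time",
          class = "knotflight_schema_error")
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- pmap(list(events$tag_id, as.list(events$departure_time),
                    seq_len(nrow(events))),
               function(tag, t_used, i) {
                 t_used <- as_utc(t_used)
                 avail <- sample_available(t_used, n_avail, window)
                 tibble(
                   event_id = paste0(tag, "#", i),
                   t = c(t_used, avail),
                   response = c(1L, rep(0L, n_avail)),
                   weight = c(1, rep(avail_weight, n_avail))
                 )
               })
  design <- list_rbind(rows)
  cov <- annotate_times(design$t, env, track_bearing)
  bind_cols(design, select(cov, -"t"))
}

#' Fit the departure resource-selection GAM
#'
#' Maximizes the case-weighted binomial log-likelihood with a logit link:
#' linear terms for pressure change, wind assistance, cloud, rain and
#' year, and penalized cubic regression spline smooths for time to sunset
#' and time to high tide. Smoothing parameters are selected by GCV by
#' default. A constant covariate (e.g. a single-year design) is dropped
#' with a message rather than an error.
#'
#' @param design A [build_rsf_design()] tibble.
#' @param k Basis dimension per smooth (default 10).
#' @param bs Spline basis (default "cr", cubic regression; use "cc" for a
#'   cyclic tidal smooth).
#' @param method mgcv smoothing-parameter criterion (default "GCV.Cp").
#' @param linear,smooth Character vectors naming the linear and smooth
#'   covariates.
#' @return Object of class `rsf_fit` wrapping the mgcv fit, with the
#'   design attached.
#' @export
fit_rsf <- function(design, k = 10, bs = "cr", method = "GCV.Cp",
                    linear = c("wind_assist", "cloud", "d_pressure",
                               "rain", "year"),
                    smooth = c("min_to_sunset", "min_to_hightide")) {
  need <- c("response", "weight", linear, smooth)
  missing <- setdiff(need, names(design))
  if (length(missing)) {
    abort(paste0("design lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "knotflight_schema_error")
  }
  if (length(unique(design$response)) < 2) {
    abort("design needs both used and available rows",
          class = "knotflight_design_error")
  }
  if (length(intersect(linear, smooth))) {
    abort("a covariate cannot be both linear and smooth",
          class = "knotflight_design_error")
  }
  if (k < 4) {
    abort("basis dimension k must be >= 4",
          class = "knotflight_parameter_error")
  }
  df <- as.data.frame(design)
  if ("year" %in% linear) {
    if (length(unique(df$year)) > 1) {
      df$year <- factor(df$year)
    } else {
      inform("single-year design: dropping the year term")
      linear <- setdiff(linear, "year")
    }
  }
  constant <- linear[vapply(linear, function(v)
    length(unique(df[[v]])) < 2, logical(1))]
  if (length(constant)) {
    inform(paste0("dropping constant covariate(s): ",
                  paste(constant, collapse = ", ")))
    linear <- setdiff(linear, constant)
  }
  rhs <- c(linear,
           sprintf("s(%s, k = %d, bs = \"%s\")", smooth, k, bs))
  fml <- stats::as.formula(paste("response ~", paste(rhs, collapse = " + ")))
  w <- df$weight
  fit <- mgcv::gam(fml, family = binomial(link = "logit"), data = df,
                   weights = w, method = method)
  if (!fit$converged) {
    abort("GAM fit did not converge", class = "knotflight_fit_error")
  }
  structure(list(gam = fit, design = as_tibble(df), linear = linear,
                 smooth = smooth, k = k, bs = bs, method = method),
            class = "rsf_fit")
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat("Departure resource-selection GAM (weighted binomial, logit link)\n")
  cat(" events:", sum(x$design$response == 1),
      " available:", sum(x$design$response == 0), "\n")
  cat(" linear terms:", paste(x$linear, collapse = ", "), "\n")
  cat(" smooth terms:", paste(x$smooth, collapse = ", "),
      sprintf(" (bs = %s, k = %d, %s)\n", x$bs, x$k, x$method))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy an RSF fit
#'
#' @param x An `rsf_fit`.
#' @param type "linear" (parametric coefficients; the default) or
#'   "smooth" (per-smooth EDF and significance).
#' @param ... Unused.
#' @return A tibble in broom layout.
#' @method tidy rsf_fit
#' @export
tidy.rsf_fit <- function(x, type = c("linear", "smooth"), ...) {
  type <- match.arg(type)
  s <- mgcv::summary.gam(x$gam)
  if (type == "linear") {
    pt <- s$p.table
    tibble(term = rownames(pt), estimate = pt[, 1], std.error = pt[, 2],
           statistic = pt[, 3], p.value = pt[, 4])
  } else {
    st <- s$s.table
    tibble(term = rownames(st), edf = st[, 1], ref.df = st[, 2],
           statistic = st[, 3], p.value = st[, 4])
  }
}

#' Fit-level summary of an RSF fit
#'
#' @param x An `rsf_fit`.
#' @param ... Unused.
#' @return One-row tibble: event counts, deviance explained, UBRE/GCV
#'   score, AIC, convergence.
#' @method glance rsf_fit
#' @export
glance.rsf_fit <- function(x, ...) {
  s <- mgcv::summary.gam(x$gam)
  tibble(n_events = sum(x$design$response == 1),
         n_available = sum(x$design$response == 0),
         deviance = as.numeric(stats::deviance(x$gam)),
         dev.expl = s$dev.expl, score = as.numeric(x$gam$gcv.ubre),
         aic = as.numeric(stats::AIC(x$gam)),
         converged = x$gam$converged)
}

reference_row <- function(fit) {
  df <- as.data.frame(fit$design)
  vars <- c(fit$linear, fit$smooth)
  out <- lapply(vars, function(v) {
    if (is.factor(df[[v]])) factor(levels(df[[v]])[1], levels(df[[v]]))
    else median(df[[v]])
  })
  setNames(as.data.frame(out), vars)
}

#' Scaled resource-selection curve for one covariate
#'
#' The exponent of the partial linear predictor of one term (all other
#' terms held at reference values, intercept excluded), min-max scaled to
#' `[0, 1]` over the evaluation grid.
#'
#' @param fit An `rsf_fit`.
#' @param covariate Name of a fitted linear or smooth covariate.
#' @param grid Optional numeric evaluation grid; default is 200 points
#'   over the observed range (smooths warn when extrapolating).
#' @return Tibble: `covariate`, `value`, `rsf` (scaled 0-1), `se`
#'   (standard error of the partial predictor, log scale).
#' @export
rsf_curve <- function(fit, covariate, grid = NULL) {
  stopifnot(inherits(fit, "rsf_fit"))
  vars <- c(fit$linear, fit$smooth)
  if (!covariate %in% vars) {
    abort(paste0(covariate, " is not a fitted covariate"),
          class = "knotflight_parameter_error")
  }
  obs <- fit$design[[covariate]]
  if (is.null(grid)) {
    grid <- seq(min(obs), max(obs), length.out = 200)
  } else if (min(grid) < min(obs) || max(grid) > max(obs)) {
    warn("curve grid extends beyond the fitted covariate range")
  }
  nd <- reference_row(fit)[rep(1, length(grid)), , drop = FALSE]
  nd[[covariate]] <- grid
  term_label <- if (covariate %in% fit$smooth) {
    paste0("s(", covariate, ")")
  } else {
    covariate
  }
  pr <- predict(fit$gam, newdata = nd, type = "terms", se.fit = TRUE)
  col <- grep(paste0("^", gsub("([()])", "\\\\\\1", term_label)),
              colnames(pr$fit), value = TRUE)[1]
  eta <- pr$fit[, col]
  w <- exp(eta)
  rng <- diff(range(w))
  scaled <- if (rng > 0) (w - min(w)) / rng else rep(0, length(w))
  tibble(covariate = covariate, value = grid, rsf = scaled,
         se = pr$se.fit[, col])
}

#' Peak of a fitted smooth
#'
#' Argmax of the fitted smooth term over a 1-min evaluation grid spanning
#' the observed covariate range.
#'
#' @param fit An `rsf_fit`.
#' @param smooth Name of a fitted smooth covariate.
#' @param flat_tol Range of the partial predictor below which the smooth
#'   is reported flat with a warning (default 1e-6).
#' @return Peak location in minutes (numeric scalar).
#' @export
peak_estimate <- function(fit, smooth, flat_tol = 1e-6) {
  if (!smooth %in% fit$smooth) {
    abort(paste0(smooth, " is not a fitted smooth"),
          class = "knotflight_parameter_error")
  }
  obs <- fit$design[[smooth]]
  grid <- seq(ceiling(min(obs)), floor(max(obs)), by = 1)
  nd <- reference_row(fit)[rep(1, length(grid)), , drop = FALSE]
  nd[[smooth]] <- grid
  pr <- predict(fit$gam, newdata = nd, type = "terms")
  col <- grep(paste0("^s\\(", smooth, "\\)"), colnames(pr), value = TRUE)[1]
  eta <- pr[, col]
  if (diff(range(eta)) < flat_tol) {
    warn(paste0("smooth ", smooth, " is flat; peak ill-defined"))
  }
  i <- which.max(eta)
  if (i == 1 || i == length(grid)) {
    warn(paste0("smooth ", smooth, " peaks at the grid boundary"))
  }
  grid[i]
}

#' Bootstrap confidence intervals for smooth peaks
#'
#' Case bootstrap by event: departure events are resampled with
#' replacement, available sets regenerated, the GAM refitted, and the
#' peaks of both smooths recorded. The interval is the 2.5/97.5 empirical
#' percentile of the `B` peak estimates.
#'
#' @param events Departure events (`tag_id`, `departure_time`).
#' @param env An [env_bundle()].
#' @param B Bootstrap replicates (default 100).
#' @param seed Optional integer.
#' @param n_avail,window,avail_weight Design settings (see
#'   [build_rsf_design()]).
#' @param max_fail_frac Abort if more than this fraction of refits error
#'   (default 0.2).
#' @param ... Passed to [fit_rsf()].
#' @return Tibble: `smooth`, `mean_peak`, `ci_lower`, `ci_upper`,
#'   `n_success`.
#' @export
bootstrap_peaks <- function(events, env, B = 100, seed = NULL,
                            n_avail = 30, window = 96, avail_weight = 1000,
                            max_fail_frac = 0.2, ...) {
  if (nrow(events) < 10) {
    abort("need at least 10 events to bootstrap",
          class = "knotflight_design_error")
  }
  if (!is.null(seed)) set.seed(seed)
  smooths <- c("min_to_sunset", "min_to_hightide")
  peaks <- matrix(NA_real_, B, 2, dimnames = list(NULL, smooths))
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(events), replace = TRUE)
    res <- try(suppressWarnings({
      d <- build_rsf_design(events[idx, ], env, n_avail = n_avail,
                            window = window, avail_weight = avail_weight)
      f <- fit_rsf(d, ...)
      vapply(smooths, function(s) peak_estimate(f, s), numeric(1))
    }), silent = TRUE)
    if (!inherits(res, "try-error")) peaks[b, ] <- res
  }
  ok <- stats::complete.cases(peaks)
  if (mean(!ok) > max_fail_frac) {
    abort(paste0(sum(!ok), " of ", B, " bootstrap refits failed"),
          class = "knotflight_fit_error")
  }
  list_rbind(lapply(smooths, function(s) {
    p <- peaks[ok, s]
    tibble(smooth = s, mean_peak = mean(p),
           ci_lower = unname(quantile(p, 0.025, type = 7)),
           ci_upper = unname(quantile(p, 0.975, type = 7)),
           n_success = sum(ok))
  }))
}

#' Sensitivity of coefficients to the number of available points
#'
#' Refits the model for each candidate availability sample size with
#' fresh available draws and reports the linear-coefficient trajectories,
#' flagging stability when every coefficient changes by less than
#' `tol_rel` between successive sizes.
#'
#' @param events Departure events.
#' @param env An [env_bundle()].
#' @param candidate_ns Availability sizes (default 5, 10, 20, 30, 50,
#'   100).
#' @param seed Optional integer.
#' @param tol_rel Relative-change threshold for the stability flag
#'   (default 0.1).
#' @param ... Passed to [fit_rsf()].
#' @return Tibble: `n_avail`, `term`, `estimate`, `std.error`, `stable`
#'   (NA for the first size).
#' @export
sensitivity_n_available <- function(events, env,
                                    candidate_ns = c(5, 10, 20, 30, 50, 100),
                                    seed = NULL, tol_rel = 0.1, ...) {
  if (!length(candidate_ns)) {
    abort("candidate_ns must be non-empty",
          class = "knotflight_parameter_error")
  }
  tabs <- lapply(candidate_ns, function(n) {
    # per-size seed: the same n always gets the same availability draw
    d <- build_rsf_design(events, env, n_avail = n,
                          seed = if (!is.null(seed)) seed + n)
    f <- fit_rsf(d, ...)
    mutate(tidy(f), n_avail = n)
  })
  prev <- NULL
  out <- list()
  for (i in seq_along(tabs)) {
    tb <- tabs[[i]]
    if (is.null(prev)) {
      tb$stable <- NA
    } else {
      m <- match(tb$term, prev$term)
      rel <- abs(tb$estimate - prev$estimate[m]) /
        pmax(abs(prev$estimate[m]), 1e-8)
      tb$stable <- all(rel < tol_rel, na.rm = TRUE)
    }
    prev <- tb
    out[[i]] <- tb
  }
  select(list_rbind(out), "n_avail", "term", "estimate", "std.error",
         "statistic", "p.value", "stable")
}
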