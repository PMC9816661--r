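#' Growth time-course dataset
#'
#' A tidy container for replicate-averaged growth data: time points, mean
#' observations `z` and standard errors `sigma`. Standard errors are floored
#' at `1e-3 * max(z)` so that early time points where replicates coincide do
#' not get infinite weight.
#'
#' @param times Strictly increasing time points.
#' @param z Mean observations.
#' @param sigma Standard errors (floored; non-negative).
#' @param unit `"cells"` or `"mm3"`.
#' @param provenance `"abm"`, `"experimental"` or `"synthetic"`.
#' @return A tibble of class `growth_data` with columns `time`, `z`, `sigma`
#'   and attributes `unit` and `provenance`.
#' @export
growth_data <- function(times, z, sigma, unit = c("cells", "mm3"),
                        provenance = c("abm", "experimental", "synthetic")) {
  unit <- match.arg(unit)
  provenance <- match.arg(provenance)
  check_that(length(times) == length(z) && length(z) == length(sigma),
             "`times`, `z`, `sigma` must have equal lengths")
  check_that(all(diff(times) > 0), "`times` must be strictly increasing")
  check_that(all(sigma >= 0), "`sigma` must be non-negative")
  sigma <- pmax(sigma, 1e-3 * max(z))
  out <- tibble::tibble(time = as.numeric(times), z = as.numeric(z),
                        sigma = as.numeric(sigma))
  attr(out, "unit") <- unit
  attr(out, "provenance") <- provenance
  class(out) <- c("growth_data", class(out))
  out
}

#' Read / write growth datasets as CSV (`time,z,sigma`)
#'
#' @param path File path.
#' @param data A [growth_data()].
#' @param ... Passed to [growth_data()] (unit, provenance).
#' @export
read_growth_data <- function(path, ...) {
  df <- utils::read.csv(path)
  check_that(all(c("time", "z", "sigma") %in% names(df)),
             "CSV must have columns time, z, sigma")
  growth_data(df$time, df$z, df$sigma, ...)
}

#' @rdname read_growth_data
#' @export
write_growth_data <- function(data, path) {
  utils::write.csv(data[, c("time", "z", "sigma")], path, row.names = FALSE)
  invisible(path)
}

#' Weighted sum of squared residuals
#'
#' `chi^2 = sum_i ((z_i - y_i(params)) / sigma_i)^2`, where `y_i` is the
#' surrogate trajectory through the data times (starting from `N0 = params$N0`
#' at the first time point).
#'
#' @param params An [sm_params()].
#' @param data A [growth_data()] (or any data frame with `time`, `z`,
#'   `sigma`).
#' @param uniform_weights Ignore `sigma` and use unit weights.
#' @return The chi-squared value.
#' @export
weighted_ssr <- function(params, data, uniform_weights = FALSE) {
  y <- sm_trajectory(params$model, params$values, params$N0, data$time)
  if (is.null(y)) rlang::abort("surrogate model could not be solved at `params`")
  w <- if (uniform_weights) rep(1, nrow(data)) else data$sigma
  sum(((data$z - y) / w)^2)
}

# Bounded minimisation: L-BFGS-B for the descent, then a derivative-free
# polish (Brent in 1-D, Nelder-Mead otherwise, with a box penalty) — the
# finite-difference gradients of L-BFGS-B stall on the sloppy ridges
# typical of growth-law fits.
minimize_chi2 <- function(start, obj, lb, ub, polish = TRUE) {
  res <- try(optim(start, obj, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 500, factr = 1e3)), silent = TRUE)
  if (inherits(res, "try-error") || !is.finite(res$value)) res <- NULL
  if (!polish) return(res)
  # polish from both the descent result and the raw start: the descent can
  # fall into boundary traps that the simplex avoids
  polish_one <- function(p0) {
    if (length(p0) == 1) {
      r <- try(optim(p0, obj, method = "Brent", lower = lb, upper = ub,
                     control = list(maxit = 1000)), silent = TRUE)
    } else {
      pen <- function(p) {
        if (any(p < lb - 1e-9) || any(p > ub + 1e-9)) return(1e12)
        obj(p)
      }
      r <- try(optim(p0, pen, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12)),
               silent = TRUE)
    }
    if (inherits(r, "try-error") || !is.finite(r$value)) return(NULL)
    r$par <- pmin(pmax(r$par, lb), ub)
    r
  }
  cands <- list(res)
  cands <- c(cands, list(polish_one(start)))
  if (!is.null(res)) cands <- c(cands, list(polish_one(res$par)))
  cands <- Filter(Negate(is.null), cands)
  if (length(cands) == 0) return(NULL)
  cands[[which.min(vapply(cands, `[[`, 1, "value"))]]
}

# Default log-uniform multi-start bounds per model parameter.
default_bounds <- function(model) {
  switch(model,
         vb = list(alpha = c(1e-3, 1e3), beta = c(1e-4, 1e2),
                   gamma = c(1e-3, 0.999)),
         gg = list(lambda = c(1e-3, 3), delta = c(1e-4, 1e2),
                   gamma = c(1e-4, 1e2)),
         gl = list(gamma = c(1e-4, 1e2), lambda = c(1e-2, 1e2),
                   K = c(1e-2, 1e9)),
         lin = list(theta = c(1e-6, 1e6)))
}

# chi^2 as a function of log-parameters; Inf where the model cannot be
# evaluated, which L-BFGS-B treats as a rejected step.
chi2_objective <- function(model, data, N0, uniform_weights = FALSE,
                           fixed = NULL) {
  w <- if (uniform_weights) rep(1, nrow(data)) else data$sigma
  free_names <- setdiff(sm_param_names(model), names(fixed))
  function(logp) {
    values <- setNames(exp(logp), free_names)
    if (!is.null(fixed)) values <- c(values, fixed)[sm_param_names(model)]
    y <- sm_trajectory(model, values, N0, data$time)
    if (is.null(y)) return(1e12)
    val <- sum(((data$z - y) / w)^2)
    if (!is.finite(val)) 1e12 else val
  }
}

#' Fit a surrogate model by weighted least squares
#'
#' Multi-start bounded minimisation of [weighted_ssr()] over log-parameters:
#' `n_starts` Latin-hypercube starts drawn log-uniformly within `bounds`,
#' each polished with `L-BFGS-B`. `N0` is fixed at the first observation, so
#' the free parameter count equals the model's parameter count (3 for all
#' three candidates).
#'
#' @param data A [growth_data()].
#' @param model Model id (see [sm_params()]).
#' @param n_starts Number of Latin-hypercube starts.
#' @param bounds Named list of `c(lower, upper)` per parameter.
#' @param N0 Initial size; defaults to the first observation.
#' @param uniform_weights Ignore `sigma` (unit weights).
#' @return An object of class `sm_fit`: `params` ([sm_params()]), `chi2`,
#'   `converged`, `n_starts`, plus the data and settings needed for
#'   profiling.
#' @examples
#' p <- sm_params("vb", c(alpha = 1.5, beta = 0.3, gamma = 0.6), N0 = 10)
#' dat <- growth_data(0:20, vb_closed_form(p, 0:20)$N, rep(1, 21))
#' fit <- fit_growth(dat, "vb", n_starts = 8)
#' @export
fit_growth <- function(data, model = "vb", n_starts = 20, bounds = NULL,
                       N0 = NULL, uniform_weights = FALSE) {
  model <- canonical_model(model)
  pnames <- sm_param_names(model)
  check_that(nrow(data) > length(pnames),
             "need more data points than free parameters")
  if (is.null(bounds)) bounds <- default_bounds(model)
  check_that(all(pnames %in% names(bounds)), "bounds must cover all parameters")
  if (is.null(N0)) N0 <- data$z[1]
  check_that(is_pos(N0), "`N0` must be positive")

  lb <- log(vapply(bounds[pnames], `[`, 1, 1))
  ub <- log(vapply(bounds[pnames], `[`, 1, 2))
  obj <- chi2_objective(model, data, N0, uniform_weights)

  starts <- lhs::randomLHS(n_starts, length(pnames))
  starts <- sweep(sweep(starts, 2, ub - lb, `*`), 2, lb, `+`)

  best <- NULL
  n_ok <- 0L
  for (s in seq_len(n_starts)) {
    res <- minimize_chi2(starts[s, ], obj, lb, ub, polish = FALSE)
    if (is.null(res)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (!is.null(best)) {
    res <- minimize_chi2(best$par, obj, lb, ub, polish = TRUE)
    if (!is.null(res) && res$value < best$value) best <- res
  }
  if (is.null(best) || best$value >= 1e12) {
    rlang::abort(sprintf(
      "fit_growth: no start converged for model %s (%d starts attempted)",
      model, n_starts))
  }
  params <- sm_params(model, setNames(exp(best$par), pnames), N0 = N0,
                      unit = attr(data, "unit") %||% "cells")
  structure(
    list(params = params, chi2 = best$value,
         converged = best$convergence == 0, n_starts = n_starts,
         n_successful_starts = n_ok,
         data = data, model = model, bounds = bounds, N0 = N0,
         uniform_weights = uniform_weights),
    class = "sm_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sm_fit <- function(x, ...) {
  cat(sprintf("<sm_fit> %s, chi2 = %.6g (%d starts)\n", x$model, x$chi2,
              x$n_starts))
  print(x$params)
  invisible(x)
}

#' @export
tidy.sm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params$values),
                 estimate = unname(x$params$values))
}

#' @export
glance.sm_fit <- function(x, ...) {
  tibble::tibble(model = x$model, chi2 = x$chi2, n = nrow(x$data),
                 k = length(x$params$values), converged = x$converged)
}

#' Plot a surrogate fit against its data
#'
#' @param object An `sm_fit`.
#' @param ... Unused.
#' @export
autoplot.sm_fit <- function(object, ...) {
  tt <- seq(min(object$data$time), max(object$data$time), length.out = 200)
  y <- sm_trajectory(object$model, object$params$values, object$N0,
                     sort(unique(c(object$data$time[1], tt))))
  curve <- tibble::tibble(time = sort(unique(c(object$data$time[1], tt))),
                          N = y)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$z)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$z - .data$sigma,
                                          ymax = .data$z + .data$sigma)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$N),
                       colour = "steelblue") +
    ggplot2::labs(x = "time", y = "size",
                  title = sprintf("%s fit, chi2 = %.4g", object$model,
                                  object$chi2))
}

#' Profile likelihood of one surrogate parameter
#'
#' Fixes the named parameter at each grid value and re-optimises the
#' remaining parameters, yielding the profile `chi^2(p)`. The 95% confidence
#' interval is delimited by the crossings (located by linear interpolation)
#' of the threshold `chi2_min + qchisq(0.95, 1)` (= `chi2_min + 3.84`). A
#' side on which the profile never exceeds the threshold is flagged
#' practically unidentifiable and its bound is `NA` (open-ended).
#'
#' The default grid is 41 log-spaced points spanning a factor of 10 either
#' side of the estimate, extended adaptively (up to `max_expand` extra
#' decades per side) until the threshold is crossed or the parameter bound is
#' hit.
#'
#' @param fit An [fit_growth()] result.
#' @param param Parameter name to profile.
#' @param grid Optional explicit grid of fixed values (must bracket the
#'   estimate).
#' @param n_grid Grid size when `grid` is `NULL`.
#' @param conf_level Confidence level for the threshold.
#' @param max_expand Maximum number of extra decades to append per side.
#' @return An object of class `sm_profile`: tibble `profile` (grid `value`,
#'   `chi2`, re-optimised parameters), `threshold`, `ci_lower`, `ci_upper`
#'   (`NA` when open-ended), `mle`, `chi2_min`.
#' @export
profile_likelihood <- function(fit, param, grid = NULL, n_grid = 41,
                               conf_level = 0.95, max_expand = 10) {
  check_that(inherits(fit, "sm_fit"), "`fit` must be an sm_fit")
  pnames <- sm_param_names(fit$model)
  check_that(param %in% pnames, paste0("unknown parameter `", param, "`"))
  check_that(isTRUE(fit$converged) || fit$chi2 < 1e12, "fit did not converge")
  mle <- fit$params$values[[param]]
  threshold <- fit$chi2 + qchisq(conf_level, df = 1)
  bounds <- fit$bounds
  pb <- bounds[[param]]

  if (is.null(grid)) {
    lo <- max(mle / 10, pb[1])
    hi <- min(mle * 10, pb[2])
    grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  } else {
    grid <- sort(grid)
    check_that(min(grid) <= mle && max(grid) >= mle,
               "`grid` must bracket the fitted estimate")
  }

  prof <- profile_sweep(fit, param, grid)
  # adaptive extension until the threshold is crossed or the bound is hit
  step <- diff(range(log(grid))) / (length(grid) - 1)
  for (side in c("lower", "upper")) {
    expand <- 0
    while (expand < max_expand) {
      v <- if (side == "lower") prof$chi2[1] else prof$chi2[nrow(prof)]
      edge <- if (side == "lower") prof$value[1] else prof$value[nrow(prof)]
      at_bound <- if (side == "lower") edge <= pb[1] * (1 + 1e-9)
      else edge >= pb[2] * (1 - 1e-9)
      if (v >= threshold || at_bound) break
      n_new <- ceiling(log(10) / step)
      new_vals <- if (side == "lower") {
        pmax(exp(log(edge) - step * seq_len(n_new)), pb[1])
      } else {
        pmin(exp(log(edge) + step * seq_len(n_new)), pb[2])
      }
      new_vals <- new_vals[new_vals > 0]
      new_prof <- profile_sweep(fit, param, new_vals)
      prof <- if (side == "lower") dplyr::bind_rows(new_prof, prof)
      else dplyr::bind_rows(prof, new_prof)
      prof <- dplyr::arrange(prof, .data$value)
      expand <- expand + 1
    }
  }

  # the re-optimizations can find a slightly better optimum than the
  # original multi-start fit; anchor the threshold (and the reported
  # estimate) at the best point seen so the interval brackets it
  chi2_min <- fit$chi2
  min_prof <- suppressWarnings(min(prof$chi2, na.rm = TRUE))
  if (is.finite(min_prof) && min_prof < chi2_min) {
    chi2_min <- min_prof
    mle <- prof$value[which.min(prof$chi2)]
  }
  threshold <- chi2_min + qchisq(conf_level, df = 1)
  ci <- profile_ci(prof$value, prof$chi2, mle, threshold)
  structure(
    list(param = param, profile = prof, threshold = threshold,
         chi2_min = chi2_min, mle = mle,
         ci_lower = ci[1], ci_upper = ci[2],
         conf_level = conf_level, fit = fit),
    class = "sm_profile"
  )
}

# Re-optimise the non-profiled parameters at each fixed grid value, warm
# starting from the previous optimum and from the MLE.
profile_sweep <- function(fit, param, grid) {
  pnames <- sm_param_names(fit$model)
  free <- setdiff(pnames, param)
  if (length(free) == 0) {
    # no nuisance parameters: the profile is the raw objective
    chi2 <- vapply(grid, function(g) {
      obj <- chi2_objective(fit$model, fit$data, fit$N0, fit$uniform_weights,
                            fixed = setNames(g, param))
      obj(numeric(0))
    }, 1)
    return(tibble::tibble(value = grid, chi2 = chi2))
  }
  lb <- log(vapply(fit$bounds[free], `[`, 1, 1))
  ub <- log(vapply(fit$bounds[free], `[`, 1, 2))
  mle_free <- log(fit$params$values[free])
  rows <- vector("list", length(grid))
  prev <- mle_free
  ordering <- order(abs(log(grid) - log(fit$params$values[[param]])))
  for (g in ordering) {
    fixed <- setNames(grid[g], param)
    obj <- chi2_objective(fit$model, fit$data, fit$N0, fit$uniform_weights,
                          fixed = fixed)
    best <- NULL
    for (start in unique(list(prev, mle_free))) {
      res <- minimize_chi2(start, obj, lb, ub, polish = TRUE)
      if (is.null(res)) next
      if (is.null(best) || res$value < best$value) best <- res
    }
    if (is.null(best)) {
      rows[[g]] <- tibble::tibble(value = grid[g], chi2 = NA_real_)
      next
    }
    prev <- best$par
    row <- tibble::tibble(value = grid[g], chi2 = best$value)
    reopt <- setNames(as.list(exp(best$par)), free)
    rows[[g]] <- dplyr::bind_cols(row, tibble::as_tibble(reopt))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$value)
}

# Threshold crossings on each side of the profile minimum. Interpolation is
# linear on the square-root scale sqrt(chi2 - chi2_min) — the profile
# likelihood-ratio statistic — which is exact for quadratic profiles and
# much more accurate than raw linear interpolation on steep ones.
profile_ci <- function(values, chi2, mle, threshold) {
  ok <- is.finite(chi2)
  values <- values[ok]
  chi2 <- chi2[ok]
  if (length(values) < 2) return(c(NA_real_, NA_real_))
  i0 <- which.min(chi2)
  s <- sqrt(pmax(chi2 - chi2[i0], 0))
  s_thr <- sqrt(max(threshold - chi2[i0], 0))
  lower <- NA_real_
  upper <- NA_real_
  if (i0 > 1) {
    for (i in rev(seq_len(i0 - 1))) {
      if (s[i] >= s_thr && s[i + 1] < s_thr) {
        lower <- values[i] + (s[i] - s_thr) / (s[i] - s[i + 1]) *
          (values[i + 1] - values[i])
        break
      }
    }
  }
  if (i0 < length(values)) {
    for (i in i0:(length(values) - 1)) {
      if (s[i] < s_thr && s[i + 1] >= s_thr) {
        upper <- values[i] + (s_thr - s[i]) / (s[i + 1] - s[i]) *
          (values[i + 1] - values[i])
        break
      }
    }
  }
  c(lower, upper)
}

#' @export
print.sm_profile <- function(x, ...) {
  cat(sprintf("<sm_profile> %s: mle = %.5g, 95%% CI [%s, %s]\n",
              x$param, x$mle,
              ifelse(is.na(x$ci_lower), "open", sprintf("%.5g", x$ci_lower)),
              ifelse(is.na(x$ci_upper), "open", sprintf("%.5g", x$ci_upper))))
  invisible(x)
}

#' @export
tidy.sm_profile <- function(x, ...) x$profile

#' @export
glance.sm_profile <- function(x, ...) {
  tibble::tibble(param = x$param, mle = x$mle, chi2_min = x$chi2_min,
                 threshold = x$threshold, ci_lower = x$ci_lower,
                 ci_upper = x$ci_upper,
                 identifiable = !is.na(x$ci_lower) & !is.na(x$ci_upper))
}

#' Plot a likelihood profile
#'
#' @param object An `sm_profile`.
#' @param ... Unused.
#' @export
autoplot.sm_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$value, y = .data$chi2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$threshold, colour = "red") +
    ggplot2::geom_vline(xintercept = object$mle, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = object$param, y = expression(chi^2),
                  title = sprintf("Profile likelihood for %s", object$param))
}

#' Practically identifiable combination between two parameters
#'
#' Fits the rational form `gamma = (beta + a) / (beta + b)` to the
#' (fixed beta, re-optimised gamma) pairs harvested from a beta profile —
#' the functional relationship that remains constrained by the data when the
#' individual parameters are not. Initialised by linear least squares (the
#' form is linear in `a`, `b` after clearing the denominator) and polished
#' with [minpack.lm::nlsLM()].
#'
#' @param profile An `sm_profile` of `beta` from a vB fit (or a data frame
#'   with columns `beta` and `gamma`).
#' @param min_points Minimum number of profile points required.
#' @return An object of class `sm_combination`: `a`, `b`, `rss`,
#'   `beta_range`, `points`, and `predict(combination, beta)` support.
#' @export
infer_combination <- function(profile, min_points = 4) {
  if (inherits(profile, "sm_profile")) {
    check_that(profile$param == "beta", "profile must be of `beta`")
    # keep the data-consistent part of the profile: re-optimisations that
    # succeeded and lie within the confidence region
    ok <- is.finite(profile$profile$chi2) &
      profile$profile$chi2 <= profile$threshold
    pts <- tibble::tibble(beta = profile$profile$value[ok],
                          gamma = profile$profile$gamma[ok])
  } else {
    pts <- tibble::as_tibble(profile)[, c("beta", "gamma")]
  }
  pts <- pts[stats::complete.cases(pts), ]
  pts <- dplyr::distinct(pts)
  check_that(nrow(pts) >= min_points,
             sprintf("need at least %d profile points", min_points))
  check_that(sd(pts$gamma) > 1e-8 * max(abs(pts$gamma)),
             "gamma is constant along the beta profile: degenerate combination fit")
  # For fixed b the optimal a is a linear least-squares solve (the residual
  # gamma - (beta + a)/(beta + b) is affine in a), so scan b over a wide
  # grid excluding poles inside the beta range, then polish with nlsLM.
  # This avoids the ill-conditioned joint fit when the points lie on a
  # beta*(1-gamma) ~ const ridge.
  rng <- range(pts$beta)
  b_grid <- c(exp(seq(log(1e-6), log(1e6), length.out = 200)),
              -rng[1] + -exp(seq(log(1e-6), log(1e6), length.out = 100)),
              -rng[2] - rev(exp(seq(log(1e-6), log(1e6), length.out = 100))))
  best <- NULL
  for (b0 in b_grid) {
    w <- 1 / (pts$beta + b0)
    if (any(!is.finite(w))) next
    r <- pts$gamma - pts$beta * w
    a0 <- sum(w * r) / sum(w * w)
    rss0 <- sum((r - a0 * w)^2)
    if (is.finite(rss0) && (is.null(best) || rss0 < best$rss)) {
      best <- list(a = a0, b = b0, rss = rss0)
    }
  }
  check_that(!is.null(best), "combination fit failed on the profile points")
  a <- best$a
  b <- best$b
  rss <- best$rss
  fit <- try(minpack.lm::nlsLM(
    gamma ~ (beta + a) / (beta + b), data = pts,
    start = list(a = a, b = b),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (!inherits(fit, "try-error")) {
    cf <- coef(fit)
    pole_inside <- -cf[["b"]] >= rng[1] && -cf[["b"]] <= rng[2]
    rss_fit <- sum(stats::residuals(fit)^2)
    if (!pole_inside && is.finite(rss_fit) && rss_fit < rss) {
      a <- cf[["a"]]; b <- cf[["b"]]; rss <- rss_fit
    }
  }
  structure(
    list(a = unname(a), b = unname(b), rss = rss,
         beta_range = range(pts$beta), points = pts),
    class = "sm_combination"
  )
}

#' @export
print.sm_combination <- function(x, ...) {
  cat(sprintf(
    "<sm_combination> gamma = (beta + %.4g) / (beta + %.4g), rss = %.3g\n",
    x$a, x$b, x$rss))
  invisible(x)
}

#' @export
predict.sm_combination <- function(object, beta, ...) {
  (beta + object$a) / (beta + object$b)
}

#' @export
tidy.sm_combination <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}
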