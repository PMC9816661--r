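#' Surrogate growth-law models
#'
#' The three candidate surrogate models (SMs) are classical tumor growth
#' laws for the total size `N(t)`:
#'
#' * generalized Gompertz (`gg`): `dN/dt = N^lambda (delta - gamma log N)`
#' * generalized logistic (`gl`): `dN/dt = gamma N (1 - (N/K)^lambda)`
#' * von Bertalanffy (`vb`):      `dN/dt = alpha N^gamma - beta N`
#'
#' A fourth, auxiliary constant-rate law (`lin`, `dN/dt = theta`) is
#' provided because its weighted least-squares problem is linear-Gaussian
#' with a closed-form solution — handy for validating the fitting and
#' profile-likelihood machinery against analytic results.
#'
#' `sm_params()` bundles a model id with named positive parameter values, an
#' initial size `N0` and a unit tag (`"cells"` or `"mm3"`).
#'
#' @param model One of `"vb"`, `"gg"`, `"gl"` (aliases
#'   `"von_bertalanffy"`, `"generalized_gompertz"`, `"generalized_logistic"`).
#' @param values Named numeric vector of positive parameter values
#'   (vb: `alpha`, `beta`, `gamma`; gg: `lambda`, `delta`, `gamma`;
#'   gl: `gamma`, `lambda`, `K`).
#' @param N0 Initial size (> 0).
#' @param unit `"cells"` or `"mm3"`.
#' @return An object of class `sm_params`.
#' @examples
#' p <- sm_params("vb", c(alpha = 1.5, beta = 0.3, gamma = 0.6), N0 = 10)
#' sm_rhs(p, c(1, 10, 100))
#' @export
sm_params <- function(model, values, N0, unit = c("cells", "mm3")) {
  model <- canonical_model(model)
  unit <- match.arg(unit)
  need <- sm_param_names(model)
  check_that(all(need %in% names(values)),
             paste0("`values` must name ", paste(need, collapse = ", ")))
  values <- values[need]
  check_that(all(is.finite(values)) && all(values > 0),
             "all surrogate parameter values must be positive")
  check_that(is_pos(N0), "`N0` must be > 0")
  structure(list(model = model, values = values, N0 = N0, unit = unit),
            class = "sm_params")
}

canonical_model <- function(model) {
  map <- c(vb = "vb", von_bertalanffy = "vb",
           gg = "gg", generalized_gompertz = "gg",
           gl = "gl", generalized_logistic = "gl",
           lin = "lin", linear = "lin")
  m <- map[tolower(model)]
  check_that(!is.na(m), paste0("unknown model `", model, "`"))
  unname(m)
}

sm_param_names <- function(model) {
  switch(model,
         vb = c("alpha", "beta", "gamma"),
         gg = c("lambda", "delta", "gamma"),
         gl = c("gamma", "lambda", "K"),
         lin = "theta")
}

#' @export
print.sm_params <- function(x, ...) {
  cat(sprintf("<sm_params> %s: %s; N0 = %g %s\n", x$model,
              paste(sprintf("%s = %g", names(x$values), x$values),
                    collapse = ", "),
              x$N0, x$unit))
  invisible(x)
}

#' Surrogate model right-hand side
#'
#' Evaluates `dN/dt` for a surrogate model at sizes `N`. The generalized
#' Gompertz rate is defined as 0 at `N = 0` (its continuous limit);
#' `gg_linear = TRUE` switches the Gompertz prefactor from `N^lambda` to
#' `lambda * N` (the alternative reading of the typeset equation).
#'
#' @param params An [sm_params()].
#' @param N Non-negative sizes.
#' @param gg_linear Use `lambda * N` instead of `N^lambda` in the Gompertz
#'   prefactor.
#' @return `dN/dt` at each `N`.
#' @export
sm_rhs <- function(params, N, gg_linear = FALSE) {
  check_that(all(N >= 0), "`N` must be non-negative")
  v <- params$values
  switch(params$model,
         vb = v[["alpha"]] * N^v[["gamma"]] - v[["beta"]] * N,
         gg = {
           pre <- if (gg_linear) v[["lambda"]] * N else N^v[["lambda"]]
           out <- pre * (v[["delta"]] - v[["gamma"]] * log(pmax(N, .Machine$double.xmin)))
           out[N == 0] <- 0
           out
         },
         gl = v[["gamma"]] * N * (1 - (N / v[["K"]])^v[["lambda"]]),
         lin = rep(v[["theta"]], length(N)))
}

#' Solve a surrogate model numerically
#'
#' Integrates the initial value problem with an adaptive stiff-capable solver
#' (`deSolve::ode`, `lsoda`, rtol 1e-8 / atol 1e-16 — growth trajectories
#' span many orders of magnitude, so the absolute tolerance is kept far
#' below any size of interest and accuracy is effectively relative) and
#' returns the
#' trajectory at the requested times.
#'
#' @inheritParams sm_rhs
#' @param times Increasing time points; the solution starts at `times[1]`
#'   with `N(times[1]) = N0`.
#' @return A tibble with columns `time` and `N`.
#' @export
sm_solve <- function(params, times, gg_linear = FALSE) {
  check_that(length(times) >= 2 && all(diff(times) > 0),
             "`times` must be increasing")
  rhs <- function(t, y, p) list(sm_rhs(params, pmax(y, 0), gg_linear))
  sol <- try(deSolve::ode(y = c(N = params$N0), times = times, func = rhs,
                          parms = NULL, method = "lsoda",
                          rtol = 1e-8, atol = 1e-16), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(times) ||
      any(!is.finite(sol[, "N"]))) {
    rlang::abort(paste0("ODE solver failed for ", params$model, " at ",
                        paste(sprintf("%s = %g", names(params$values),
                                      params$values), collapse = ", ")))
  }
  tibble::tibble(time = times, N = as.numeric(sol[, "N"]))
}

#' von Bertalanffy closed-form solution
#'
#' The vB equation `dN/dt = alpha N^gamma - beta N` is a Bernoulli ODE with
#' solution `N(t)^(1-gamma) = alpha/beta + (N0^(1-gamma) - alpha/beta)
#' exp(-beta (1-gamma) t)`. For `|1 - gamma| < 1e-6` the exponential limit
#' `N0 exp((alpha - beta) t)` is used.
#'
#' @param params An [sm_params()] with `model = "vb"`.
#' @param times Time points (relative to `times[1]`, where `N = N0`).
#' @return A tibble with columns `time` and `N`.
#' @export
vb_closed_form <- function(params, times) {
  check_that(params$model == "vb", "`params` must be a vB parameterisation")
  v <- params$values
  t0 <- times - times[1]
  e <- 1 - v[["gamma"]]
  if (abs(e) < 1e-6) {
    N <- params$N0 * exp((v[["alpha"]] - v[["beta"]]) * t0)
  } else {
    A <- v[["alpha"]] / v[["beta"]]
    core <- A + (params$N0^e - A) * exp(-v[["beta"]] * e * t0)
    N <- core^(1 / e)
  }
  tibble::tibble(time = times, N = as.numeric(N))
}

# Fast trajectory used inside fitting loops: closed forms for vB (Bernoulli
# solution), GL (Richards substitution u = (N/K)^lambda reduces to a
# logistic) and the linear law; log-space integration with rejection guards
# for GG. Returns NULL on failure instead of aborting, so optimizers treat
# bad parameter corners as rejected steps.
sm_trajectory <- function(model, values, N0, times) {
  if (model == "lin") {
    return(N0 + values[["theta"]] * (times - times[1]))
  }
  if (model == "gl") {
    la <- values[["lambda"]]
    ga <- values[["gamma"]]
    K <- values[["K"]]
    u0 <- (N0 / K)^la
    if (!is.finite(u0) || u0 <= 0) return(NULL)
    ex <- exp(-la * ga * (times - times[1]))
    u <- u0 / (u0 + (1 - u0) * ex)
    if (any(!is.finite(u)) || any(u <= 0)) return(NULL)
    N <- K * u^(1 / la)
    if (any(!is.finite(N))) return(NULL)
    return(N)
  }
  if (model == "gg") {
    la <- values[["lambda"]]
    de <- values[["delta"]]
    ga <- values[["gamma"]]
    vstar <- de / ga  # log-scale plateau
    v0 <- log(N0)
    # reject absurd corners (plateau beyond e^60, or an explosive
    # prefactor) rather than grinding the integrator through them
    vmax <- max(v0, vstar)
    if (vstar > 60 || (la - 1) * vmax > 50) return(NULL)
    rhs <- function(t, v, p) list(exp((la - 1) * v) * (de - ga * v))
    sol <- try(suppressWarnings(
      deSolve::ode(c(v = v0), times, rhs, NULL, method = "lsoda",
                   rtol = 1e-8, atol = 1e-10, maxsteps = 10000)),
      silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < length(times)) return(NULL)
    v <- sol[, "v"]
    if (any(!is.finite(v)) || any(v > 700)) return(NULL)
    return(exp(v))
  }
  if (model == "vb") {
    e <- 1 - values[["gamma"]]
    t0 <- times - times[1]
    if (abs(e) < 1e-6) {
      N <- N0 * exp((values[["alpha"]] - values[["beta"]]) * t0)
    } else {
      A <- values[["alpha"]] / values[["beta"]]
      core <- A + (N0^e - A) * exp(-values[["beta"]] * e * t0)
      if (any(core <= 0)) return(NULL)
      N <- core^(1 / e)
    }
    if (any(!is.finite(N))) return(NULL)
    return(N)
  }
  p <- structure(list(model = model, values = values, N0 = N0,
                      unit = "cells"), class = "sm_params")
  out <- try(sm_solve(p, times), silent = TRUE)
  if (inherits(out, "try-error")) return(NULL)
  out$N
}

#' Information criteria from a residual sum of squares
#'
#' Gaussian concentrated-likelihood forms: with the default `form = "rss"`,
#' `AIC = n log(rss/n) + 2k` and `BIC = n log(rss/n) + k log(n)`; with
#' `form = "loglik"` the constant Gaussian terms `n log(2 pi) + n` are added
#' to both. Additive constants cancel in model comparisons.
#'
#' @param rss Residual (here: weighted) sum of squares, > 0.
#' @param n Number of data points.
#' @param k Number of fitted parameters (`n > k >= 1`).
#' @param model Optional model id carried through to the output.
#' @param form Concentrated-likelihood constant convention.
#' @return A one-row tibble: `model`, `rss`, `n`, `k`, `aic`, `bic`.
#' @examples
#' information_criteria(10, n = 30, k = 3)
#' @export
information_criteria <- function(rss, n, k, model = NA_character_,
                                 form = c("rss", "loglik")) {
  form <- match.arg(form)
  check_that(is_pos(rss), "`rss` must be > 0 (rss = 0 is a degenerate perfect fit)")
  check_that(n > k && k >= 1, "need n > k >= 1")
  base <- n * log(rss / n)
  if (form == "loglik") base <- base + n * log(2 * pi) + n
  tibble::tibble(model = model, rss = rss, n = as.integer(n),
                 k = as.integer(k), aic = base + 2 * k,
                 bic = base + k * log(n))
}

#' Fit candidate surrogates and rank them by information criteria
#'
#' Fits each candidate model to each dataset with [fit_growth()] and returns
#' per-dataset scores together with an aggregate score per model (weighted
#' RSS and n summed over datasets, k = parameters-per-fit x datasets), the
#' aggregation used to score a model against a family of ABM-generated
#' time-courses.
#'
#' @param datasets A named list of [growth_data()] tibbles.
#' @param models Candidate model ids.
#' @param n_starts Multi-start count passed to [fit_growth()].
#' @param form Information-criterion convention, see
#'   [information_criteria()].
#' @return An object of class `sm_selection`: list with `per_dataset` and
#'   `aggregate` tibbles and `best` (model id with minimum aggregate AIC).
#' @export
select_model <- function(datasets, models = c("vb", "gg", "gl"),
                         n_starts = 20, form = c("rss", "loglik")) {
  form <- match.arg(form)
  check_that(length(models) >= 2, "need at least two candidate models")
  check_that(length(datasets) > 0, "need at least one dataset")
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset_", seq_along(datasets))
  }
  models_c <- vapply(models, canonical_model, "")
  rows <- list()
  for (m in models_c) {
    for (d in names(datasets)) {
      dat <- datasets[[d]]
      k <- length(sm_param_names(m))
      check_that(nrow(dat) > k, "each dataset needs more points than parameters")
      fit <- fit_growth(dat, model = m, n_starts = n_starts)
      sc <- information_criteria(fit$chi2, n = nrow(dat), k = k, model = m,
                                 form = form)
      sc$dataset <- d
      rows[[length(rows) + 1L]] <- sc
    }
  }
  per_dataset <- dplyr::bind_rows(rows) %>%
    dplyr::select("model", "dataset", "rss", "n", "k", "aic", "bic")
  aggregate <- per_dataset %>%
    dplyr::group_by(.data$model) %>%
    dplyr::summarise(rss = sum(.data$rss), n = sum(.data$n),
                     k = sum(.data$k), .groups = "drop")
  agg_scores <- purrr::pmap(aggregate, function(model, rss, n, k) {
    information_criteria(rss, n, k, model = model, form = form)
  }) %>% dplyr::bind_rows()
  best <- agg_scores$model[which.min(agg_scores$aic)]
  structure(list(per_dataset = per_dataset, aggregate = agg_scores,
                 best = best),
            class = "sm_selection")
}

#' @export
print.sm_selection <- function(x, ...) {
  cat("<sm_selection> aggregate scores:\n")
  print(as.data.frame(x$aggregate), row.names = FALSE)
  cat(sprintf("best model by AIC: %s\n", x$best))
  invisible(x)
}

#' @export
tidy.sm_selection <- function(x, ...) x$per_dataset

#' @export
glance.sm_selection <- function(x, ...) {
  dplyr::mutate(x$aggregate, best = .data$model == x$best)
}
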