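#' Nonlinear growth model specifications
#'
#' The five classical growth functions used for weight-age data. All are
#' parameterised by the mature (asymptotic) weight `A` (kg), the integration
#' constant `b` (unitless, fixes the curve at age zero) and the maturity rate
#' `K` (reciprocal of the age unit); Richards adds the inflection exponent
#' `M`.
#'
#' Functional forms:
#' * brody: `w = A (1 - b e^{-Kt})`
#' * bertalanffy: `w = A (1 - b e^{-Kt})^3`
#' * logistic: `w = A (1 + b e^{-Kt})^{-1}`
#' * gompertz: `w = A exp(-b e^{-Kt})`
#' * richards: `w = A (1 + s b e^{-Kt})^M` with sign `s = -1` by default
#'
#' @param name One of `"brody"`, `"bertalanffy"`, `"logistic"`,
#'   `"gompertz"`, `"richards"`.
#' @param richards_sign Sign convention for the Richards base, `-1` or `+1`.
#' @return A `growth_model` object: name, number of parameters, parameter
#'   names, prediction function and analytic Jacobian.
#' @export
growth_model <- function(name = c("brody", "bertalanffy", "logistic",
                                  "gompertz", "richards"),
                         richards_sign = -1) {
  name <- match.arg(name)
  par_names <- if (name == "richards") c("A", "b", "K", "M") else c("A", "b", "K")
  spec <- list(name = name, n_params = length(par_names),
               par_names = par_names, richards_sign = richards_sign)
  class(spec) <- "growth_model"
  spec
}

#' Evaluate a growth model at given ages
#'
#' Exact evaluation of the model's functional form; see [growth_model()].
#'
#' @param model A [growth_model()] object or a model name.
#' @param params Named numeric vector (A, b, K and, for Richards, M).
#' @param t Numeric vector of ages (same unit as used at fitting time).
#' @return Predicted weights (kg).
#' @export
predict_weight <- function(model, params, t) {
  if (is.character(model)) model <- growth_model(model)
  A <- params[["A"]]; b <- params[["b"]]; K <- params[["K"]]
  e <- exp(-K * t)
  switch(model$name,
    brody = A * (1 - b * e),
    bertalanffy = A * (1 - b * e)^3,
    logistic = A / (1 + b * e),
    gompertz = A * exp(-b * e),
    richards = {
      g <- 1 + model$richards_sign * b * e
      if (any(g <= 0))
        stop("richards base (1 + s*b*exp(-Kt)) is non-positive: ",
             "fractional exponent would be complex")
      A * g^params[["M"]]
    })
}

# Analytic Jacobian d w / d params, rows = ages, cols = parameters.
model_jacobian <- function(model, params, t) {
  A <- params[["A"]]; b <- params[["b"]]; K <- params[["K"]]
  e <- exp(-K * t)
  switch(model$name,
    brody = cbind(A = 1 - b * e, b = -A * e, K = A * b * t * e),
    bertalanffy = {
      g <- 1 - b * e
      cbind(A = g^3, b = -3 * A * g^2 * e, K = 3 * A * g^2 * b * t * e)
    },
    logistic = {
      h <- 1 + b * e
      cbind(A = 1 / h, b = -A * e / h^2, K = A * b * t * e / h^2)
    },
    gompertz = {
      f <- exp(-b * e)
      cbind(A = f, b = -A * e * f, K = A * b * t * e * f)
    },
    richards = {
      s <- model$richards_sign; M <- params[["M"]]
      g <- 1 + s * b * e
      cbind(A = g^M, b = A * M * g^(M - 1) * s * e,
            K = -A * M * g^(M - 1) * s * b * t * e,
            M = A * g^M * log(g))
    })
}

# TRUE when the parameter vector lies in the model's admissible domain.
params_valid <- function(model, params, t) {
  if (any(!is.finite(params))) return(FALSE)
  if (params[["A"]] <= 0 || params[["K"]] <= 0 || params[["b"]] <= 0)
    return(FALSE)
  if (model$name == "richards") {
    g <- 1 + model$richards_sign * params[["b"]] * exp(-params[["K"]] * t)
    if (any(g <= 0)) return(FALSE)
  }
  TRUE
}

#' Starting values for a growth-curve fit
#'
#' `A0 = 1.1 * max(weight)`; `b0` solved from the first observation given
#' `A0` and each candidate `K`; `K0` minimises the SSE over the grid
#' `seq(0.005, 0.5, by = 0.005)`; Richards starts at `M0 = 1`. A series with
#' no net growth (last weight not above the first) falls back to
#' `A0 = max(weight)` and the smallest grid `K`, with a warning.
#'
#' @param series A [weight_series()].
#' @param model A [growth_model()] object or name.
#' @return Named numeric vector of starting values.
#' @export
initial_estimates <- function(series, model) {
  if (is.character(model)) model <- growth_model(model)
  t <- series$ages; w <- series$weights
  if (length(w) < model$n_params)
    stop("need at least ", model$n_params, " observations for ", model$name)
  grid <- seq(0.005, 0.5, by = 0.005)
  fallback <- w[length(w)] <= w[1L] || max(w) <= min(w)
  A0 <- if (fallback) max(w) else 1.1 * max(w)
  if (fallback)
    warning("non-increasing weight series for animal ", series$animal_id,
            ": falling back to A0 = max weight, smallest grid K")

  b_from_first <- function(K) {
    e1 <- exp(-K * t[1L])
    ratio <- min(w[1L] / A0, 1 - 1e-9)
    b <- switch(model$name,
      brody = (1 - ratio) / e1,
      bertalanffy = (1 - ratio^(1 / 3)) / e1,
      logistic = (1 / ratio - 1) / e1,
      gompertz = -log(ratio) / e1,
      richards = (1 - ratio) / e1)  # M0 = 1 reduces to the brody form
    max(b, 1e-6)
  }

  if (fallback) {
    K0 <- grid[1L]
  } else {
    sse <- vapply(grid, function(K) {
      p <- c(A = A0, b = b_from_first(K), K = K)
      if (model$name == "richards") p <- c(p, M = 1)
      pr <- tryCatch(predict_weight(model, p, t), error = function(e) NULL)
      if (is.null(pr) || any(!is.finite(pr))) return(Inf)
      sum((w - pr)^2)
    }, numeric(1L))
    K0 <- grid[which.min(sse)]
  }
  p0 <- c(A = A0, b = b_from_first(K0), K = K0)
  if (model$name == "richards") p0 <- c(p0, M = 1)
  p0
}

#' Fit one growth model to one animal by nonlinear least squares
#'
#' Gauss-Newton iterations with a Levenberg-Marquardt damping ladder
#' (damping multiplied by 10 on each rejected step, divided by 10 on each
#' accepted one). Convergence is declared when the largest relative
#' parameter change falls below `tol`. A fit that exhausts `max_iter` or
#' whose damped normal equations stay singular is returned with
#' `converged = FALSE` (it counts against the population convergence rate).
#'
#' @param series A [weight_series()]; must have at least as many points as
#'   parameters.
#' @param model A [growth_model()] object or name.
#' @param settings List with `max_iter` (default 200) and `tol`
#'   (default 1e-8).
#' @param start Optional starting values; default [initial_estimates()].
#' @return A `growth_fit`: animal id, model name, parameter estimates,
#'   convergence flag and, when converged, diagnostics from [gof_summary()].
#' @export
fit_animal <- function(series, model, settings = list(), start = NULL) {
  if (is.character(model)) model <- growth_model(model)
  max_iter <- settings$max_iter %||% 200L
  tol <- settings$tol %||% 1e-8
  t <- series$ages; w <- series$weights
  n <- length(w); p <- model$n_params
  fit <- list(animal_id = series$animal_id, model = model$name,
              params = NULL, converged = FALSE, diagnostics = NULL)
  class(fit) <- "growth_fit"
  if (n < p) return(fit)

  theta <- tryCatch(
    withCallingHandlers(
      if (is.null(start)) initial_estimates(series, model) else start,
      warning = function(wrn) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (is.null(theta) || !params_valid(model, theta, t)) return(fit)

  sse_at <- function(th) {
    if (!params_valid(model, th, t)) return(Inf)
    r <- w - predict_weight(model, th, t)
    if (any(!is.finite(r))) return(Inf)
    sum(r^2)
  }
  sse <- sse_at(theta)
  lambda <- 1e-4
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    r <- w - predict_weight(model, theta, t)
    J <- model_jacobian(model, theta, t)
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    accepted <- FALSE
    for (k in 1:15) {  # damping ladder
      H <- JtJ + lambda * diag(pmax(diag(JtJ), 1e-12), p)
      delta <- tryCatch(drop(solve(H, g)), error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta))) {
        cand <- theta + delta
        sse_new <- sse_at(cand)
        if (sse_new <= sse) {
          rel <- max(abs(delta) / (abs(theta) + 1e-10))
          theta <- cand; sse <- sse_new
          lambda <- max(lambda / 10, 1e-12)
          accepted <- TRUE
          if (rel < tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted || converged) break
  }
  fit$params <- theta
  # a fit pinned at the b floor has degenerated to a constant curve: the
  # parameters are not identifiable, so it does not count as converged
  fit$converged <- converged && params_valid(model, theta, t) &&
    theta[["b"]] > 1e-5
  if (fit$converged && n > p)
    fit$diagnostics <- gof_summary(series, fit)
  fit
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit>", x$animal_id, x$model,
      if (x$converged) "converged" else "NOT converged", "\n")
  if (!is.null(x$params)) print(round(x$params, 6))
  invisible(x)
}

#' Goodness-of-fit battery for a converged growth fit
#'
#' Residual-based diagnostics: `mse = SSE/(n-p)`,
#' `r2_adj = 1 - (SSE/(n-p)) / (SST/(n-1))`,
#' `aic = n log(SSE/n) + 2(p+1)` (Gaussian likelihood with estimated
#' residual variance; SSE floored at 1e-12 so a perfect fit stays finite),
#' and the mean absolute deviation over the early (`mad1`) and late (`mad2`)
#' curve segments. By default the segments split at the median age, which on
#' the 0/6/12/15/18/24-month design puts birth-12 months in `mad1` and
#' 15-24 months in `mad2`.
#'
#' @param series A [weight_series()].
#' @param fit A `growth_fit` (or a list with `model` and `params`).
#' @param mad_split Age cutoff separating the two MAD segments
#'   (ages `<= mad_split` go to `mad1`); default the median age.
#' @return A list with `r2_adj`, `mse`, `mad1`, `mad2`, `aic`, `sse` and the
#'   per-age `residuals`.
#' @export
gof_summary <- function(series, fit, mad_split = NULL) {
  t <- series$ages; w <- series$weights
  n <- length(w)
  model <- if (is.character(fit$model)) growth_model(fit$model) else fit$model
  p <- model$n_params
  if (n <= p) stop("need n > p observations for diagnostics (n = ", n,
                   ", p = ", p, ")")
  if (is.null(mad_split)) mad_split <- stats::median(t)
  resid <- w - predict_weight(model, fit$params, t)
  sse <- sum(resid^2)
  sst <- sum((w - mean(w))^2)
  early <- t <= mad_split
  list(
    r2_adj = 1 - (sse / (n - p)) / (sst / (n - 1)),
    mse = sse / (n - p),
    mad1 = mean(abs(resid[early])),
    mad2 = mean(abs(resid[!early])),
    aic = n * log(max(sse, 1e-12) / n) + 2 * (p + 1),
    sse = sse,
    residuals = stats::setNames(resid, t)
  )
}

#' Fit a growth model to every animal and summarise the population
#'
#' Animals flagged incomplete, or with fewer points than parameters, are not
#' attempted. The convergence rate C% is `100 * converged / attempted`;
#' parameter and diagnostic means/SDs are taken over converged animals only.
#'
#' @param phenos List of [weight_series()].
#' @param model A [growth_model()] object or name.
#' @param settings Passed to [fit_animal()].
#' @return List with `fits` (one `growth_fit` per attempted animal) and
#'   `summary` (a `population_fit_summary`).
#' @export
fit_population <- function(phenos, model, settings = list()) {
  if (is.character(model)) model <- growth_model(model)
  attempted <- Filter(function(w) w$complete &&
                        length(w$weights) >= model$n_params, phenos)
  if (length(attempted) == 0L) stop("no complete series to fit")
  fits <- lapply(attempted, fit_animal, model = model, settings = settings)
  conv <- vapply(fits, function(f) f$converged, logical(1L))
  grab <- function(field, diag = FALSE) {
    vapply(fits[conv], function(f)
      if (diag) f$diagnostics[[field]] else f$params[[field]], numeric(1L))
  }
  stat_cols <- c(model$par_names,
                 c("r2_adj", "mse", "mad1", "mad2", "aic"))
  means <- sds <- stats::setNames(rep(NA_real_, length(stat_cols)), stat_cols)
  if (any(conv)) {
    for (nm in model$par_names) {
      v <- grab(nm); means[nm] <- mean(v); sds[nm] <- stats::sd(v)
    }
    for (nm in c("r2_adj", "mse", "mad1", "mad2", "aic")) {
      v <- grab(nm, diag = TRUE); means[nm] <- mean(v); sds[nm] <- stats::sd(v)
    }
  }
  summary <- structure(
    list(model = model$name, n_attempted = length(fits),
         n_converged = sum(conv),
         convergence_pct = 100 * mean(conv),
         means = means, sds = sds),
    class = "population_fit_summary")
  list(fits = fits, summary = summary)
}

#' @export
print.population_fit_summary <- function(x, ...) {
  cat("<population_fit_summary>", x$model, "\n")
  cat(sprintf("  C%% = %.2f (%d / %d)\n", x$convergence_pct,
              x$n_converged, x$n_attempted))
  tab <- rbind(mean = x$means, sd = x$sds)
  print(round(tab, 4))
  invisible(x)
}

#' Rank candidate growth models by goodness of fit
#'
#' Models with a convergence rate below `min_convergence_pct` are excluded
#' before ranking (a model that rarely converges is useless regardless of its
#' fit, as with Richards on 6-point cattle data). The remaining models are
#' scored by how many of five criteria they win outright: highest mean
#' adjusted R-squared, lowest mean MSE, lowest mean MAD1, lowest mean MAD2,
#' lowest mean AIC. Ties in the win count break by lower mean AIC.
#'
#' @param summaries List of `population_fit_summary` objects (>= 2 for a
#'   meaningful comparison; a single model is returned rank 1).
#' @param min_convergence_pct Exclusion threshold on C% (default 50).
#' @return A data.frame ordered by rank with one row per retained model.
#' @export
select_model <- function(summaries, min_convergence_pct = 50) {
  keep <- Filter(function(s) s$convergence_pct >= min_convergence_pct,
                 summaries)
  if (length(keep) == 0L)
    stop("all models excluded by the C% >= ", min_convergence_pct,
         " convergence filter")
  crit <- data.frame(
    model = vapply(keep, function(s) s$model, character(1L)),
    convergence_pct = vapply(keep, function(s) s$convergence_pct, numeric(1L)),
    r2_adj = vapply(keep, function(s) s$means[["r2_adj"]], numeric(1L)),
    mse = vapply(keep, function(s) s$means[["mse"]], numeric(1L)),
    mad1 = vapply(keep, function(s) s$means[["mad1"]], numeric(1L)),
    mad2 = vapply(keep, function(s) s$means[["mad2"]], numeric(1L)),
    aic = vapply(keep, function(s) s$means[["aic"]], numeric(1L)),
    stringsAsFactors = FALSE)
  wins <- integer(nrow(crit))
  award <- function(values, lower_is_better) {
    best <- if (lower_is_better) min(values) else max(values)
    which(values == best)
  }
  for (idx in list(award(crit$r2_adj, FALSE), award(crit$mse, TRUE),
                   award(crit$mad1, TRUE), award(crit$mad2, TRUE),
                   award(crit$aic, TRUE)))
    if (length(idx) == 1L) wins[idx] <- wins[idx] + 1L
  crit$criteria_won <- wins
  ord <- order(-crit$criteria_won, crit$aic, crit$model)
  crit <- crit[ord, , drop = FALSE]
  crit$rank <- seq_len(nrow(crit))
  rownames(crit) <- NULL
  crit
}

`%||%` <- function(a, b) if (is.null(a)) b else a
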