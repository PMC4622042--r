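test_that("model predictions match their closed forms at age zero", {
  expect_equal(predict_weight("brody", c(A = 520.32, b = 0.92, K = 0.06), 0),
               520.32 * (1 - 0.92))  # 41.6256
  expect_equal(predict_weight("logistic", c(A = 400, b = 4.85, K = 0.2), 0),
               400 / 5.85)           # 68.376...
  expect_equal(predict_weight("gompertz", c(A = 300, b = 2, K = 0.1), 0),
               300 * exp(-2))
  expect_equal(predict_weight("bertalanffy", c(A = 300, b = 0.5, K = 0.1), 0),
               300 * 0.5^3)
  expect_equal(predict_weight("richards", c(A = 300, b = 0.5, K = 0.1, M = 2), 0),
               300 * 0.5^2)
})

test_that("brody approaches its asymptote and richards rejects complex bases", {
  p <- c(A = 500, b = 0.9, K = 0.06)
  expect_equal(predict_weight("brody", p, 1000), 500, tolerance = 1e-9)
  expect_error(predict_weight("richards", c(A = 1, b = 3, K = 0.01, M = 0.5), 0),
               "complex")
})

test_that("noiseless data are recovered to 1e-6 for all five models", {
  set.seed(401)
  ages <- c(0, 6, 12, 15, 18, 24)
  draws <- 20L
  for (mn in c("brody", "bertalanffy", "logistic", "gompertz", "richards")) {
    for (r in seq_len(draws)) {
      p <- switch(mn,
        brody = c(A = runif(1, 300, 700), b = runif(1, 0.7, 0.97),
                  K = runif(1, 0.03, 0.15)),
        bertalanffy = c(A = runif(1, 300, 700), b = runif(1, 0.3, 0.6),
                        K = runif(1, 0.05, 0.2)),
        logistic = c(A = runif(1, 300, 700), b = runif(1, 2, 8),
                     K = runif(1, 0.1, 0.3)),
        gompertz = c(A = runif(1, 300, 700), b = runif(1, 1, 3),
                     K = runif(1, 0.08, 0.25)),
        richards = c(A = runif(1, 300, 700), b = runif(1, 0.5, 0.9),
                     K = runif(1, 0.05, 0.2), M = runif(1, 1, 3)))
      f <- fit_animal(series_from_model(mn, p, ages), mn)
      expect_true(f$converged, info = paste(mn, r))
      expect_lt(max(abs(f$params[names(p)] - p) / pmax(abs(p), 1)), 1e-6)
    }
  }
})

test_that("per-animal fit agrees with an independent NLS implementation", {
  skip_if_not_installed("minpack.lm")
  set.seed(402)
  ages <- c(0, 6, 12, 15, 18, 24)
  truth <- c(A = 500, b = 0.9, K = 0.07)
  ws <- series_from_model("brody", truth, ages, noise_sd = 5)
  f <- fit_animal(ws, "brody")
  ref <- minpack.lm::nlsLM(
    w ~ A * (1 - b * exp(-K * t)),
    data = data.frame(t = ages, w = ws$weights),
    start = as.list(initial_estimates(ws, "brody")))
  expect_true(f$converged)
  expect_equal(unname(f$params[c("A", "b", "K")]),
               unname(coef(ref)[c("A", "b", "K")]), tolerance = 1e-5)
})

test_that("starting values obey their construction", {
  ages <- c(0, 6, 12, 15, 18, 24)
  ws <- series_from_model("brody", c(A = 450, b = 0.9, K = 0.08), ages)
  p0 <- initial_estimates(ws, "brody")
  expect_gte(p0[["A"]], max(ws$weights))        # A0 >= max observed always
  # the grid argmin compensates for the deliberately inflated A0, so K0
  # lands within a couple of grid steps of the truth and the subsequent
  # fit still recovers it exactly
  expect_lte(abs(p0[["K"]] - 0.08), 0.0101)
  f <- fit_animal(ws, "brody", start = p0)
  expect_true(f$converged)
  expect_equal(unname(f$params[["K"]]), 0.08, tolerance = 1e-7)
  # constant weights take the fallback path with a warning
  flat <- weight_series("flat", ages, rep(100, 6))
  expect_warning(p0f <- initial_estimates(flat, "brody"), "falling back")
  expect_equal(p0f[["A"]], 100)
  expect_equal(p0f[["K"]], 0.005)
})

test_that("degenerate series fail softly instead of raising", {
  ages <- c(0, 6, 12, 15, 18, 24)
  flat <- weight_series("flat", ages, rep(100, 6))
  f <- suppressWarnings(fit_animal(flat, "richards"))
  expect_false(f$converged)
  short <- weight_series("s", c(0, 6), c(30, 200))
  expect_false(fit_animal(short, "brody")$converged)
})

test_that("goodness-of-fit arithmetic matches the hand example", {
  ages <- c(0, 6, 12, 15, 18, 24)
  p <- c(A = 500, b = 0.9, K = 0.07)
  resid <- c(1, -1, 1, -1, 1, -1)
  w <- predict_weight("brody", p, ages) + resid
  ws <- weight_series("h", ages, w)
  d <- gof_summary(ws, list(model = "brody", params = p))
  expect_equal(d$sse, 6)
  expect_equal(d$mse, 2)          # 6 / (6 - 3)
  expect_equal(d$mad1, 1)
  expect_equal(d$mad2, 1)
  expect_equal(d$aic, 6 * log(1) + 8)  # = 8
  # perfect fit floors the AIC instead of -Inf
  ws2 <- series_from_model("brody", p, ages)
  d2 <- gof_summary(ws2, list(model = "brody", params = p))
  expect_equal(d2$mse, 0)
  expect_equal(d2$r2_adj, 1)
  expect_equal(d2$aic, 6 * log(1e-12 / 6) + 8)
  expect_error(gof_summary(weight_series("x", c(0, 6, 12), c(30, 100, 200)),
                           list(model = "brody", params = p)), "n > p")
})

test_that("diagnostics are invariant to the order records arrive in", {
  set.seed(403)
  ages <- c(0, 6, 12, 15, 18, 24)
  p <- c(A = 500, b = 0.9, K = 0.07)
  w <- predict_weight("brody", p, ages) + rnorm(6, 0, 4)
  # records presented shuffled through the long-format reader end up in the
  # same canonical series, so all residual summaries agree
  tmp <- tempfile(fileext = ".csv")
  ord <- sample(6)
  writeLines(c("animal,age,weight",
               paste("a1", ages[ord], w[ord], sep = ",")), tmp)
  ws <- read_phenotypes(tmp, layout = "long")[[1]]
  d1 <- gof_summary(weight_series("a1", ages, w),
                    list(model = "brody", params = p))
  d2 <- gof_summary(ws, list(model = "brody", params = p))
  expect_equal(d1[c("mse", "mad1", "mad2", "aic")],
               d2[c("mse", "mad1", "mad2", "aic")])
})

test_that("population summary counts convergence and a flat mixture halves C%", {
  set.seed(404)
  ages <- c(0, 6, 12, 15, 18, 24)
  ok <- lapply(1:20, function(i)
    series_from_model("brody", c(A = runif(1, 400, 600), b = 0.9, K = 0.07),
                      ages, id = paste0("g", i)))
  flat <- lapply(1:20, function(i)
    weight_series(paste0("f", i), ages, rep(100 + i, 6)))
  fp <- suppressWarnings(fit_population(c(ok, flat), "brody"))
  expect_equal(fp$summary$n_attempted, 40L)
  expect_lt(abs(fp$summary$convergence_pct - 50), 15)
  # zero-noise cohort: C% = 100 and means equal truth
  fp2 <- fit_population(ok, "brody")
  expect_equal(fp2$summary$convergence_pct, 100)
  expect_equal(fp2$summary$means[["b"]], 0.9, tolerance = 1e-6)
  expect_equal(fp2$summary$means[["K"]], 0.07, tolerance = 1e-6)
})

test_that("model ranking applies the five-criterion win count and tie rules", {
  mk <- function(model, r2, mse, mad1, mad2, aic, cpct = 99) {
    structure(list(model = model, n_attempted = 100, n_converged = cpct,
                   convergence_pct = cpct,
                   means = c(A = 0, b = 0, K = 0, r2_adj = r2, mse = mse,
                             mad1 = mad1, mad2 = mad2, aic = aic),
                   sds = NULL), class = "population_fit_summary")
  }
  # the four printed model columns: Gompertz, Logistic, Brody, von Bertalanffy
  tab <- list(mk("gompertz", 0.96, 604.91, 27.53, 10.95, 42.90, 100),
              mk("logistic", 0.95, 821.16, 32.83, 10.51, 44.81, 99.44),
              mk("brody", 0.98, 382.79, 18.94, 10.28, 40.01, 99.92),
              mk("bertalanffy", 0.87, 2071.96, 46.61, 11.87, 50.42, 99.52),
              mk("richards", 0.99, 300, 10, 9, 39, 9))  # C% < 10: excluded
  sel <- select_model(tab)
  expect_false("richards" %in% sel$model)
  expect_equal(sel$model[1], "brody")
  expect_equal(sel$criteria_won[1], 5L)
  # identical criteria: deterministic AIC/name tie-break
  sel2 <- select_model(list(mk("m1", 0.9, 10, 1, 1, 20),
                            mk("m2", 0.9, 10, 1, 1, 20)))
  expect_equal(sel2$model, c("m1", "m2"))
  expect_equal(select_model(list(mk("only", 0.9, 10, 1, 1, 20)))$rank, 1L)
  expect_error(select_model(list(mk("bad", 0.9, 10, 1, 1, 20, cpct = 10))),
               "excluded")
})

test_that("fixed-effect pre-adjustment removes planted offsets, keeps means", {
  set.seed(405)
  ages <- c(0, 6, 12, 15, 18, 24)
  base <- predict_weight("brody", c(A = 500, b = 0.9, K = 0.07), ages)
  mk <- function(id, grp, off) weight_series(id, ages, base + off,
                                             factors = list(cg = grp))
  phenos <- c(lapply(1:10, function(i) mk(paste0("p", i), "g1", 10)),
              lapply(1:10, function(i) mk(paste0("q", i), "g2", -10)))
  adj <- preadjust_fixed_effects(phenos, "cg")
  wa <- weights_matrix(adj)
  g1 <- colMeans(wa[1:10, ]); g2 <- colMeans(wa[11:20, ])
  expect_lt(max(abs(g1 - g2)), 1e-9)        # planted offset removed
  expect_equal(colMeans(wa), colMeans(weights_matrix(phenos)),
               tolerance = 1e-9)            # grand means preserved
  # single-level factor: identity
  one <- lapply(1:5, function(i)
    weight_series(paste0("o", i), ages, base + i,
                  factors = list(cg = "same")))
  adj1 <- preadjust_fixed_effects(one, "cg")
  expect_equal(weights_matrix(adj1), weights_matrix(one))
})

test_that("pre-adjustment equals an independent normal-equations solve", {
  set.seed(406)
  ages <- c(0, 6, 12)
  n <- 30
  grp <- sample(c("a", "b", "c"), n, replace = TRUE)
  phenos <- lapply(seq_len(n), function(i)
    weight_series(sprintf("x%02d", i), ages,
                  abs(rnorm(3, c(30, 200, 250), 10)) + 1,
                  factors = list(cg = grp[i])))
  adj <- preadjust_fixed_effects(phenos, "cg")
  wm <- weights_matrix(phenos); wa <- weights_matrix(adj)
  X <- model.matrix(~ factor(grp))
  for (j in 1:3) {
    beta <- solve(crossprod(X), crossprod(X, wm[, j]))  # normal equations
    res <- wm[, j] - X %*% beta
    expect_equal(unname(wa[, j]), unname(mean(wm[, j]) + drop(res)),
                 tolerance = 1e-9)
  }
  # perfectly confounded factor errors
  solo <- lapply(seq_len(4), function(i)
    weight_series(paste0("s", i), ages, c(30, 200, 250),
                  factors = list(cg = paste0("lvl", i))))
  expect_error(preadjust_fixed_effects(solo, "cg"), "confounded")
})
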