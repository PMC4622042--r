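# Multivariate animal-model REML on the eigen-rotated system.
#
# Model per trait j: y_j = mu_j + u_j + e_j with u ~ N(0, Su (x) A) and
# e ~ N(0, Se (x) I). Eigendecomposing A = U D U' and rotating each trait's
# phenotype by U' turns the 3n x 3n system into n independent q x q
# problems: y*_i ~ N(c_i beta, V_i), V_i = d_i Su + Se, c_i = (U'1)_i.
# All per-record quantities below are stacks of q x q matrices stored as
# n x q x q arrays and manipulated with vectorised loops over trait pairs.

# stack of q x q inverses + log-determinants; closed-form for q <= 3
stack_inv <- function(V) {
  n <- dim(V)[1L]; q <- dim(V)[2L]
  if (q == 1L) {
    v <- V[, 1L, 1L]
    inv <- array(1 / v, c(n, 1L, 1L))
    return(list(inv = inv, logdet = log(v)))
  }
  if (q == 2L) {
    a <- V[, 1, 1]; b <- V[, 1, 2]; d <- V[, 2, 2]
    det <- a * d - b * b
    inv <- array(0, c(n, 2L, 2L))
    inv[, 1, 1] <- d / det; inv[, 2, 2] <- a / det
    inv[, 1, 2] <- inv[, 2, 1] <- -b / det
    return(list(inv = inv, logdet = log(det)))
  }
  if (q == 3L) {
    a <- V[, 1, 1]; b <- V[, 1, 2]; c <- V[, 1, 3]
    d <- V[, 2, 2]; e <- V[, 2, 3]; f <- V[, 3, 3]
    A11 <- d * f - e * e; A12 <- c * e - b * f; A13 <- b * e - c * d
    det <- a * A11 + b * A12 + c * A13
    inv <- array(0, c(n, 3L, 3L))
    inv[, 1, 1] <- A11 / det
    inv[, 1, 2] <- inv[, 2, 1] <- A12 / det
    inv[, 1, 3] <- inv[, 3, 1] <- A13 / det
    inv[, 2, 2] <- (a * f - c * c) / det
    inv[, 2, 3] <- inv[, 3, 2] <- (b * c - a * e) / det
    inv[, 3, 3] <- (a * d - b * b) / det
    return(list(inv = inv, logdet = log(det)))
  }
  # generic fallback
  inv <- array(0, c(n, q, q)); logdet <- numeric(n)
  for (i in seq_len(n)) {
    M <- matrix(V[i, , ], q, q)
    inv[i, , ] <- solve(M)
    logdet[i] <- determinant(M, logarithm = TRUE)$modulus
  }
  list(inv = inv, logdet = logdet)
}

# stack (n x q x q) times per-record vector (n x q) -> n x q
stack_matvec <- function(S, x) {
  q <- dim(S)[2L]
  out <- matrix(0, nrow(x), q)
  for (j in seq_len(q))
    for (k in seq_len(q))
      out[, j] <- out[, j] + S[, j, k] * x[, k]
  out
}

# weighted sum over records of a stack: sum_i w_i S_i -> q x q
stack_wsum <- function(S, w) {
  q <- dim(S)[2L]
  out <- matrix(0, q, q)
  for (j in seq_len(q))
    for (k in seq_len(q))
      out[j, k] <- sum(w * S[, j, k])
  out
}

# weighted sum of S_i %*% Mid %*% S_i over records (Mid fixed q x q)
stack_sandwich_sum <- function(S, Mid, w) {
  q <- dim(S)[2L]
  B <- array(0, dim(S))
  for (j in seq_len(q))
    for (k in seq_len(q))
      for (l in seq_len(q))
        B[, j, k] <- B[, j, k] + S[, j, l] * Mid[l, k]
  out <- matrix(0, q, q)
  for (j in seq_len(q))
    for (k in seq_len(q))
      for (l in seq_len(q))
        out[j, k] <- out[j, k] + sum(w * B[, j, l] * S[, l, k])
  out
}

sympart <- function(M) (M + t(M)) / 2

# clip a symmetric matrix to the PSD cone; returns matrix + flag
psd_project <- function(M, floor = 0) {
  M <- sympart(M)
  ed <- eigen(M, symmetric = TRUE)
  if (min(ed$values) >= floor) return(list(mat = M, projected = FALSE))
  vals <- pmax(ed$values, floor)
  list(mat = sympart(ed$vectors %*% (vals * t(ed$vectors))), projected = TRUE)
}

# restricted log-likelihood pieces for given (Su, Se); returns everything
# the EM step reuses so each candidate evaluation costs one pass
reml_eval <- function(d, cvec, ystar, Su, Se) {
  n <- nrow(ystar); q <- ncol(ystar)
  V <- outer(d, Su)
  for (j in seq_len(q)) for (k in seq_len(q)) V[, j, k] <- V[, j, k] + Se[j, k]
  si <- stack_inv(V)
  Vinv <- si$inv
  ty <- stack_matvec(Vinv, ystar)
  M <- stack_wsum(Vinv, cvec^2)                  # X' V^-1 X
  b1 <- drop(crossprod(ty, cvec))                # X' V^-1 y
  beta <- solve(M, b1)
  Cbeta <- solve(M)
  r <- ystar - outer(cvec, beta)
  tr <- stack_matvec(Vinv, r)
  quad <- sum(r * tr)
  loglik <- -0.5 * (sum(si$logdet) + quad +
                    determinant(M, logarithm = TRUE)$modulus[1L])
  list(loglik = loglik, Vinv = Vinv, beta = beta, Cbeta = Cbeta,
       r = r, tr = tr)
}

# one EM-REML update from a reml_eval state
reml_em_step <- function(d, cvec, st, Su, Se) {
  n <- nrow(st$r); q <- ncol(st$r)
  Vinv <- st$Vinv; tr <- st$tr; Cb <- st$Cbeta
  # genetic part: sum_i E[u_i u_i'] / d_i
  a <- tr %*% Su                                   # (V^-1 r)' Su, n x q
  Su_quad <- crossprod(a * sqrt(d))                # sum d_i a_i a_i'
  P1 <- stack_wsum(Vinv, d)                        # sum d_i V_i^-1
  Qd <- stack_sandwich_sum(Vinv, Cb, cvec^2 * d)   # sum c^2 d V^-1 Cb V^-1
  Su_new <- (Su_quad + n * Su - Su %*% P1 %*% Su + Su %*% Qd %*% Su) / n
  # residual part
  b <- tr %*% Se
  Se_quad <- crossprod(b)
  Q0 <- stack_sandwich_sum(Vinv, Cb, cvec^2)
  Se_new <- (Se_quad + sympart(Su %*% P1 %*% Se) + Se %*% Q0 %*% Se) / n
  list(Su = sympart(Su_new), Se = sympart(Se_new))
}

#' REML variance components for the multi-trait animal model (no SNP term)
#'
#' Estimates the genetic covariance `sigma_u` and residual covariance
#' `sigma_e` of the q-trait animal model with a per-trait overall mean as
#' the only fixed effect, a pedigree polygenic effect with covariance
#' `sigma_u (x) A`, and i.i.d. residuals `sigma_e (x) I`. The phenotyped
#' subset of the relationship matrix is eigendecomposed once; phenotypes
#' are rotated so that the likelihood factorises over eigenvalues; EM-REML
#' iterations (each guaranteed not to decrease the restricted likelihood)
#' run until the change in restricted log-likelihood drops below `tol`. An
#' extrapolated (doubled) EM step is tried each iteration and kept only
#' when it improves the likelihood, which preserves monotonicity while
#' roughly halving the iteration count.
#'
#' @param y Numeric matrix, animals x traits, rownames = animal ids, no
#'   missing cells (only fully fitted animals enter the trait matrix).
#' @param rel Relationship matrix covering (at least) the animals in `y`.
#' @param max_iter Maximum EM iterations (default 500); exceeding it
#'   returns `converged = FALSE` with the last estimates.
#' @param tol Convergence tolerance on the restricted log-likelihood change
#'   (default 1e-8).
#' @return A `variance_components` object: `sigma_u`, `sigma_e`, `loglik`,
#'   `loglik_trace`, `converged`, `iterations`, and `psd_projected` flags.
#' @export
reml_null <- function(y, rel, max_iter = 500L, tol = 1e-8) {
  y <- as.matrix(y)
  stopifnot(!is.null(rownames(y)), all(is.finite(y)))
  n <- nrow(y); q <- ncol(y)
  if (n < 30L) stop("need at least 30 phenotyped animals for REML")
  Asub <- rel_subset(rel, rownames(y))
  ed <- eigen(sympart(Asub), symmetric = TRUE)
  d <- pmax(ed$values, 0)
  U <- ed$vectors
  # work on unit-variance traits: the EM is scale-equivariant in exact
  # arithmetic but trait variances spanning many orders of magnitude
  # (kg^2 vs per-month^2) wreck the 3x3 solves in floating point
  scale_sd <- apply(y, 2L, stats::sd)
  if (any(scale_sd <= 0)) stop("constant trait column")
  y <- sweep(y, 2L, scale_sd, "/")
  ystar <- crossprod(U, y)
  cvec <- drop(crossprod(U, rep(1, n)))

  S <- stats::cov(y)
  floor_mag <- 1e-8 * mean(diag(S))
  Su <- S / 2; Se <- S / 2
  st <- reml_eval(d, cvec, ystar, Su, Se)
  trace <- st$loglik
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    upd <- reml_em_step(d, cvec, st, Su, Se)
    Su1 <- upd$Su
    Se1 <- psd_project(upd$Se, floor_mag)$mat  # keep V_i invertible
    st1 <- tryCatch(reml_eval(d, cvec, ystar, Su1, Se1),
                    error = function(e) NULL)
    if (is.null(st1) || !is.finite(st1$loglik)) break
    # doubling extrapolation, accepted only on improvement
    Su2 <- psd_project(Su + 2 * (Su1 - Su), 0)$mat
    Se2 <- psd_project(Se + 2 * (Se1 - Se), floor_mag)$mat
    st2 <- tryCatch(reml_eval(d, cvec, ystar, Su2, Se2),
                    error = function(e) NULL)
    if (!is.null(st2) && is.finite(st2$loglik) && st2$loglik > st1$loglik) {
      Su <- Su2; Se <- Se2; st_new <- st2
    } else {
      Su <- Su1; Se <- Se1; st_new <- st1
    }
    if (st_new$loglik < utils::tail(trace, 1L) - 1e-6)
      warning("restricted log-likelihood decreased at iteration ", it,
              " (numerical); estimates may be at a boundary")
    delta <- st_new$loglik - utils::tail(trace, 1L)
    trace <- c(trace, st_new$loglik)
    st <- st_new
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  pu <- psd_project(Su, 0); pe <- psd_project(Se, 0)
  D <- diag(scale_sd, q)
  back <- function(M) structure(D %*% M %*% D,
                                dimnames = list(colnames(y), colnames(y)))
  # restricted likelihood on the original scale differs by the Jacobian of
  # the per-trait rescaling applied to the n - 1 error contrasts
  jac <- (n - 1) * sum(log(scale_sd))
  structure(list(
    sigma_u = back(pu$mat),
    sigma_e = back(pe$mat),
    loglik = utils::tail(trace, 1L) - jac, loglik_trace = trace - jac,
    converged = converged, iterations = length(trace) - 1L,
    psd_projected = c(sigma_u = pu$projected, sigma_e = pe$projected)),
    class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components>",
      if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "iterations; logLik =",
      format(x$loglik, digits = 8), "\n")
  cat("sigma_u:\n"); print(round(x$sigma_u, 5))
  cat("sigma_e:\n"); print(round(x$sigma_e, 5))
  invisible(x)
}

#' Heritabilities and genetic correlations from variance components
#'
#' `h2_j = sigma2_u(j) / (sigma2_u(j) + sigma2_e(j))` and
#' `r_g(j,k) = sigma_u(j,k) / sqrt(sigma2_u(j) sigma2_u(k))`. A trait with
#' zero genetic variance yields `NA` correlations (undefined), reported as
#' missing rather than guessed.
#'
#' @param vc A `variance_components` object.
#' @return List with `h2` (named vector) and `r_g` (correlation matrix).
#' @export
genetic_parameters <- function(vc) {
  vu <- diag(vc$sigma_u); ve <- diag(vc$sigma_e)
  h2 <- vu / (vu + ve)
  sd_u <- sqrt(vu)
  denom <- outer(sd_u, sd_u)
  r_g <- vc$sigma_u / denom
  r_g[!is.finite(r_g)] <- NA_real_
  diag(r_g) <- 1
  r_g <- pmin(pmax(r_g, -1), 1)
  nm <- colnames(vc$sigma_u)
  list(h2 = stats::setNames(h2, nm),
       r_g = structure(r_g, dimnames = list(nm, nm)))
}
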