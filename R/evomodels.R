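#' Model-implied among-species covariance matrices
#'
#' Builds the N x N among-species covariance implied by an evolutionary
#' model, as a transformation of the Brownian-motion matrix C (shared
#' root-to-MRCA path lengths):
#' \describe{
#'   \item{BM}{C itself: unconstrained drift at constant rate.}
#'   \item{delta}{element-wise `C^delta * T^(1-delta)` (T = tree depth).
#'     A power transform of node depths: delta < 1 concentrates change near
#'     the root, delta > 1 near the tips; total depth is preserved so the
#'     rate stays comparable across models.}
#'   \item{EB}{early burst, rate `sigma^2 e^{r t}`: a shared-path segment
#'     contributes `(e^{r s} - 1)/r`, reducing to `s` as r -> 0.}
#'   \item{OU}{attraction of strength alpha toward a single optimum on an
#'     ultrametric tree: `V[i,j] = e^{-2 alpha (T - s)} (1 - e^{-2 alpha s})
#'     / (2 alpha)` with s the shared path length; tends to C as
#'     alpha -> 0.}
#'   \item{delta_OU}{the combined model: the delta depth-power transform is
#'     applied to the shared times first, then the OU transform.}
#' }
#'
#' @param tree a rooted `ape::phylo` tree with branch lengths (ultrametric
#'   for OU and delta_OU).
#' @param model one of `"BM"`, `"OU"`, `"EB"`, `"delta"`, `"delta_OU"`.
#' @param params named list; uses `alpha` (>= 0), `delta` (> 0), `r` as the
#'   model requires.
#' @return N x N covariance matrix with tip-label dimnames.
#' @export
transform_covariance <- function(tree, model = c("BM", "OU", "EB", "delta", "delta_OU"),
                                 params = list()) {
  model <- match.arg(model)
  C <- phylo_covariance(tree)
  transform_C(C, model, params,
              ultra = is_ultrametric(tree))
}

# same transforms starting from a precomputed C (hot path for fitting)
transform_C <- function(C, model, params, ultra = TRUE) {
  Tdepth <- max(diag(C))
  if (model == "BM") return(C)
  if (model == "delta") {
    d <- params$delta
    if (is.null(d) || d <= 0) stop("delta must be > 0")
    return(C^d * Tdepth^(1 - d))
  }
  if (model == "EB") {
    r <- params$r
    if (is.null(r)) stop("EB needs parameter r")
    if (abs(r) < 1e-12) return(C)
    return((exp(r * C) - 1) / r)
  }
  if (!ultra) stop("OU transform requires an ultrametric tree")
  a <- params$alpha
  if (is.null(a) || a < 0) stop("alpha must be >= 0")
  S <- C
  if (model == "delta_OU") {
    d <- params$delta
    if (is.null(d) || d <= 0) stop("delta must be > 0")
    S <- S^d * Tdepth^(1 - d)
  }
  if (a < 1e-12) return(S)
  exp(-2 * a * (Tdepth - S)) * (1 - exp(-2 * a * S)) / (2 * a)
}

n_params_for <- function(model) {
  # sigma2 + pooled root state, plus one shape parameter per transform,
  # two for the combined model
  switch(model, BM = 2L, OU = 3L, EB = 3L, delta = 3L, delta_OU = 4L)
}

# profiled pooled-rate Gaussian log-likelihood given V; returns loglik with
# the GLS root vector and pooled sigma2 as attributes
pooled_loglik_V <- function(X, V) {
  N <- nrow(X); p <- ncol(X)
  ch <- tryCatch(chol(V), error = function(e)
    stop("model covariance is numerically singular"))
  logdet <- 2 * sum(log(diag(ch)))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, N)))
  denom <- sum(Vi_1)
  a_hat <- as.vector(crossprod(X, Vi_1)) / denom
  R <- sweep(X, 2, a_hat)
  Vi_R <- Vi_X - tcrossprod(Vi_1, a_hat)
  rss <- sum(R * Vi_R)
  s2 <- rss / (N * p)
  data_scale <- sum(X^2) / (N * p)
  if (!is.finite(s2) || s2 <= 1e-15 * (data_scale + 1e-300))
    stop("degenerate data: pooled rate estimate is zero")
  ll <- -0.5 * (N * p * log(2 * pi * s2) + p * logdet + N * p)
  attr(ll, "sigma2") <- s2
  attr(ll, "root") <- a_hat
  ll
}

#' Pooled multivariate log-likelihood of an evolutionary model
#'
#' Gaussian log-likelihood of tip data under the model-implied among-species
#' covariance, with independent traits sharing a single pooled rate: per
#' trait the root state is the GLS estimate, and the common sigma^2 is
#' profiled out as the average GLS residual quadratic form over all N x p
#' observations. This is the pooled-rate formulation behind the
#' sigma^2_mult multivariate rate.
#'
#' @param data N x p trait matrix with species rownames.
#' @param tree a rooted `ape::phylo` tree.
#' @param model,params as in [transform_covariance()].
#' @return the log-likelihood (scalar), with attributes `sigma2` (pooled
#'   rate) and `root` (GLS root state per trait).
#' @export
pooled_loglik <- function(data, tree, model = "BM", params = list()) {
  X <- match_to_tips(tree, data)
  V <- transform_covariance(tree, model, params)
  pooled_loglik_V(X, V)
}

#' Fit an evolutionary model to multivariate shape data
#'
#' Maximizes the pooled log-likelihood over the model's shape parameter by
#' deterministic bounded search: Brent's method for the single-parameter
#' models (OU: alpha in [1e-8, 50/T]; delta: delta in [0.01, 3]; EB: r in
#' [-10/T, 10/T], with T the tree depth), and box-constrained optimization
#' from a fixed start grid for the joint (delta, alpha) of the combined
#' model. sigma^2 and the root state are profiled analytically.
#'
#' @param data N x p trait matrix with species rownames.
#' @param tree a rooted `ape::phylo` tree (ultrametric for OU/delta_OU).
#' @param model one of `"BM"`, `"OU"`, `"EB"`, `"delta"`, `"delta_OU"`.
#' @return an `evo_model_fit`: list with `model`, `sigma2`, `alpha`, `delta`,
#'   `r` (NA where not applicable), `root`, `loglik`, `n_params`, `aic`,
#'   `n`, `p`.
#' @export
fit_model <- function(data, tree, model = c("BM", "OU", "EB", "delta", "delta_OU")) {
  model <- match.arg(model)
  X <- match_to_tips(tree, data)
  C <- phylo_covariance(tree)
  ultra <- is_ultrametric(tree)
  Tdepth <- max(diag(C))
  if (model %in% c("OU", "delta_OU") && !ultra)
    stop("OU-type models require an ultrametric tree")
  ll_at <- function(params) {
    V <- transform_C(C, model, params, ultra = ultra)
    tryCatch(pooled_loglik_V(X, V), error = function(e) {
      ll <- -1e10; attr(ll, "sigma2") <- NA_real_; attr(ll, "root") <- NA; ll
    })
  }
  par <- list()
  if (model == "BM") {
    ll <- ll_at(list())
  } else if (model == "OU") {
    opt <- stats::optimize(function(a) as.numeric(ll_at(list(alpha = a))),
                           interval = c(1e-8, 50 / Tdepth), maximum = TRUE,
                           tol = 1e-10)
    par$alpha <- opt$maximum
    ll <- ll_at(par)
  } else if (model == "delta") {
    opt <- stats::optimize(function(d) as.numeric(ll_at(list(delta = d))),
                           interval = c(0.01, 3), maximum = TRUE, tol = 1e-10)
    par$delta <- opt$maximum
    ll <- ll_at(par)
  } else if (model == "EB") {
    opt <- stats::optimize(function(r) as.numeric(ll_at(list(r = r))),
                           interval = c(-10 / Tdepth, 10 / Tdepth),
                           maximum = TRUE, tol = 1e-12)
    par$r <- opt$maximum
    ll <- ll_at(par)
  } else {
    lower <- c(0.01, 1e-8); upper <- c(3, 50 / Tdepth)
    starts <- rbind(c(0.5, 0.5 / Tdepth), c(1, 1e-6), c(2, 1 / Tdepth),
                    c(2, 5 / Tdepth), c(0.8, 5 / Tdepth))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      o <- tryCatch(stats::optim(starts[s, ], function(th)
        -as.numeric(ll_at(list(delta = th[1], alpha = th[2]))),
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("combined-model optimization failed")
    par$delta <- best$par[1]; par$alpha <- best$par[2]
    ll <- ll_at(par)
  }
  np <- n_params_for(model)
  fit <- list(model = model,
              sigma2 = attr(ll, "sigma2"),
              alpha = if (is.null(par$alpha)) NA_real_ else par$alpha,
              delta = if (is.null(par$delta)) NA_real_ else par$delta,
              r = if (is.null(par$r)) NA_real_ else par$r,
              root = attr(ll, "root"),
              loglik = as.numeric(ll),
              n_params = np,
              aic = 2 * np - 2 * as.numeric(ll),
              n = nrow(X), p = ncol(X))
  class(fit) <- "evo_model_fit"
  fit
}

#' @export
print.evo_model_fit <- function(x, ...) {
  cat(sprintf("%s fit: logLik = %.4f, AIC = %.4f, sigma2 = %.4g\n",
              x$model, x$loglik, x$aic, x$sigma2))
  pars <- c(alpha = x$alpha, delta = x$delta, r = x$r)
  pars <- pars[!is.na(pars)]
  if (length(pars))
    cat(paste(sprintf("  %s = %.6g", names(pars), pars), collapse = "\n"), "\n")
  invisible(x)
}

#' Select the best model by AIC
#'
#' Returns the fit with the lowest AIC; ties (within `tol`) are broken
#' toward fewer parameters.
#'
#' @param fits list of `evo_model_fit` objects on identical data.
#' @param tol AIC tie tolerance.
#' @return list with `best` (the selected fit) and `table` (data frame of
#'   model, n_params, loglik, aic, delta_aic, sorted by AIC).
#' @export
select_model <- function(fits, tol = 1e-8) {
  if (length(fits) < 2L) stop("need at least 2 fits to compare")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  np <- vapply(fits, `[[`, integer(1), "n_params")
  ord <- order(aic, np)
  best_i <- ord[1]
  # explicit tie-break toward parsimony
  ties <- which(abs(aic - aic[best_i]) <= tol)
  if (length(ties) > 1L) best_i <- ties[which.min(np[ties])]
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    n_params = np,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = aic,
    delta_aic = aic - min(aic)
  )
  tab <- tab[order(tab$aic, tab$n_params), ]
  rownames(tab) <- NULL
  list(best = fits[[best_i]], table = tab)
}

#' Pooled multivariate Brownian rate sigma^2_mult
#'
#' The average Brownian rate of a trait along each dimension of morphospace:
#' the pooled GLS residual quadratic form under the BM covariance, divided
#' by N x p. Equals the profiled BM rate of [pooled_loglik()].
#'
#' @param data N x p trait matrix with species rownames.
#' @param tree a rooted `ape::phylo` tree.
#' @return scalar rate per unit branch length.
#' @export
sigma_mult <- function(data, tree) {
  as.numeric(attr(pooled_loglik(data, tree, "BM"), "sigma2"))
}

#' Reduce tangent coordinates to leading principal components
#'
#' Procrustes tangent data are rank-deficient (4 similarity dimensions are
#' lost, and often N < 2k). For covariance-based model fitting the data are
#' rotated to the principal components capturing at least `var_frac` of the
#' total variance. Scores keep species rownames; the rotation and center are
#' attached as attributes.
#'
#' @param X N x q matrix.
#' @param var_frac minimum fraction of variance retained.
#' @return N x p score matrix (p <= q) with attributes `rotation`, `center`,
#'   `var_explained`.
#' @export
reduce_dimensions <- function(X, var_frac = 0.95) {
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  keep <- which(cumsum(v) / sum(v) >= var_frac - 1e-12)[1]
  keep <- max(keep, 2L)
  S <- pc$x[, seq_len(keep), drop = FALSE]
  rownames(S) <- rownames(X)
  attr(S, "rotation") <- pc$rotation[, seq_len(keep), drop = FALSE]
  attr(S, "center") <- pc$center
  attr(S, "var_explained") <- sum(v[seq_len(keep)]) / sum(v)
  S
}
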