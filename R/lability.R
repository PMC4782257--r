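#' Build a P-matrix from reconstructed ancestral shapes or contrasts
#'
#' The phenotypic covariance matrix used as a proxy for the additive-genetic
#' G-matrix in Lande's equation. With `source = "ancestral_nodes"` it is the
#' covariance across the reconstructed internal-node shape vectors (the
#' default reading of a P-matrix "of the ancestral reconstruction"); with
#' `source = "contrasts"` it is the covariance of independent contrasts --
#' an evolutionary rate matrix.
#'
#' @param states matrix of internal-node ancestral states
#'   (from [ancestral_states()]) or of contrasts (from [pic_matrix()]).
#' @param source `"ancestral_nodes"` or `"contrasts"`.
#' @param trait_means optional trait-mean vector for later standardization;
#'   defaults to the root row (node N+1) for ancestral states, otherwise to
#'   the column means.
#' @return a `p_matrix`: list with `matrix` (p x p), `trait_means`,
#'   `standardized = FALSE`, `source`.
#' @export
build_p_matrix <- function(states, source = c("ancestral_nodes", "contrasts"),
                           trait_means = NULL) {
  source <- match.arg(source)
  states <- as.matrix(states)
  if (nrow(states) < 3L) stop("need at least 3 rows to estimate a P-matrix")
  P <- stats::cov(states)
  P <- (P + t(P)) / 2
  if (is.null(trait_means)) {
    trait_means <- if (source == "ancestral_nodes" && !is.null(rownames(states)))
      states[1, ] else colMeans(states)
  }
  out <- list(matrix = P, trait_means = as.numeric(trait_means),
              standardized = FALSE, source = source)
  class(out) <- "p_matrix"
  out
}

#' Mean-standardize a P-matrix
#'
#' Divides each element by the outer product of trait means,
#' `P[i,j] / (m_i m_j)`, making evolvability a proportional, dimensionless
#' quantity. Procrustes tangent coordinates can be arbitrarily close to
#' zero, so means smaller in magnitude than `epsilon` times the norm of the
#' mean vector are floored at that bound (keeping their sign) before
#' dividing.
#'
#' @param P a `p_matrix` (or plain matrix).
#' @param trait_means trait means; taken from `P` if absent.
#' @param epsilon floor for small means, as a fraction of the mean-vector
#'   norm.
#' @return a standardized `p_matrix`.
#' @export
mean_standardize <- function(P, trait_means = NULL, epsilon = 1e-3) {
  if (inherits(P, "p_matrix")) {
    if (is.null(trait_means)) trait_means <- P$trait_means
    M <- P$matrix
    src <- P$source
  } else {
    M <- as.matrix(P)
    src <- "unknown"
  }
  if (is.null(trait_means)) stop("trait_means required")
  m <- as.numeric(trait_means)
  bound <- epsilon * sqrt(sum(m^2))
  if (bound <= 0 || all(abs(m) < bound))
    stop("trait means too close to zero: mean standardization is meaningless")
  sgn <- ifelse(m >= 0, 1, -1)
  m2 <- sgn * pmax(abs(m), bound)
  Ms <- M / outer(m2, m2)
  out <- list(matrix = (Ms + t(Ms)) / 2, trait_means = m,
              standardized = TRUE, source = src)
  class(out) <- "p_matrix"
  out
}

#' Random-skewers lability indexes
#'
#' Probes a covariance matrix with random unit selection gradients beta
#' (normalized Gaussian draws, uniform on the sphere) and the responses
#' `dz = P beta`:
#' respondability is the mean response length `mean(|dz|)`; evolvability the
#' mean projection of the response on the selection gradient
#' `mean(beta' P beta)`; flexibility the mean cosine between response and
#' selection gradient. Monte-Carlo standard errors are reported for each.
#'
#' @param P a `p_matrix` or plain symmetric PSD matrix (p >= 2).
#' @param n_vectors number of selection gradients (default 1000).
#' @param seed integer seed.
#' @return a `skewers_result`: list with `respondability`, `evolvability`,
#'   `flexibility`, `n_vectors`, `seed`, `mc_se` (named vector).
#' @export
random_skewers <- function(P, n_vectors = 1000L, seed = 1L) {
  M <- if (inherits(P, "p_matrix")) P$matrix else as.matrix(P)
  p <- nrow(M)
  if (p < 2L) stop("need p >= 2 traits")
  if (max(abs(M - t(M))) > 1e-8 * max(abs(M), 1e-300))
    stop("P must be symmetric")
  ev_min <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(sum(diag(M)), 1e-300))
    stop("P is not positive semi-definite")
  if (all(M == 0)) stop("zero matrix: flexibility undefined")
  set.seed(as.integer(seed))
  B <- matrix(stats::rnorm(p * n_vectors), p, n_vectors)
  B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  Z <- M %*% B
  rlen <- sqrt(colSums(Z^2))
  e <- colSums(B * Z)          # beta' P beta
  f <- ifelse(rlen > 0, e / rlen, NA_real_)  # cosine: beta is unit
  mc_se <- c(respondability = stats::sd(rlen),
             evolvability = stats::sd(e),
             flexibility = stats::sd(f, na.rm = TRUE)) / sqrt(n_vectors)
  out <- list(respondability = mean(rlen),
              evolvability = mean(e),
              flexibility = mean(f, na.rm = TRUE),
              n_vectors = as.integer(n_vectors),
              seed = as.integer(seed),
              mc_se = mc_se)
  class(out) <- "skewers_result"
  out
}

#' @export
print.skewers_result <- function(x, ...) {
  cat(sprintf(paste0("random skewers (%d vectors, seed %d):\n",
                     "  respondability = %.6g (se %.2g)\n",
                     "  evolvability   = %.6g (se %.2g)\n",
                     "  flexibility    = %.6g (se %.2g)\n"),
              x$n_vectors, x$seed,
              x$respondability, x$mc_se["respondability"],
              x$evolvability, x$mc_se["evolvability"],
              x$flexibility, x$mc_se["flexibility"]))
  invisible(x)
}

#' One-row lability report for a skull region
#'
#' @param P the `p_matrix` used.
#' @param skewers a `skewers_result`.
#' @param region region label.
#' @return a one-row data frame (region, respondability, evolvability,
#'   flexibility, n_vectors, seed, source, standardized).
#' @export
lability_report <- function(P, skewers, region) {
  data.frame(region = region,
             respondability = skewers$respondability,
             evolvability = skewers$evolvability,
             flexibility = skewers$flexibility,
             n_vectors = skewers$n_vectors,
             seed = skewers$seed,
             source = if (inherits(P, "p_matrix")) P$source else NA_character_,
             standardized = if (inherits(P, "p_matrix")) P$standardized else NA,
             stringsAsFactors = FALSE)
}
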