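#' Multivariate evolutionary allometry from independent contrasts
#'
#' Least-squares regression, through the origin, of shape contrasts on
#' size contrasts (contrasts have no intercept by construction). The
#' percentage of shape variance explained is the predicted sum of squares
#' over the total sum of squares, pooled over all shape dimensions.
#'
#' @param shape_pics (N-1) x q matrix of shape contrasts.
#' @param size_pics length N-1 vector of log-centroid-size contrasts.
#' @return list with `coefficients` (length-q slope vector per unit log
#'   size) and `percent_variance` (0-100).
#' @export
fit_allometry <- function(shape_pics, size_pics) {
  shape_pics <- as.matrix(shape_pics)
  size_pics <- as.numeric(size_pics)
  if (nrow(shape_pics) != length(size_pics))
    stop("shape and size contrasts must have matching rows")
  ss <- sum(size_pics^2)
  if (ss <= 0) stop("size contrasts are all zero")
  b <- as.vector(crossprod(shape_pics, size_pics)) / ss
  pred_ss <- sum(b^2) * ss
  tot_ss <- sum(shape_pics^2)
  if (tot_ss <= 0) stop("shape contrasts are all zero")
  list(coefficients = b, percent_variance = 100 * pred_ss / tot_ss)
}

#' Permutation test for evolutionary allometry
#'
#' Significance of the shape-on-size regression assessed by randomly
#' reshuffling the size contrasts against the shape rows and recomputing the
#' percentage of shape variance explained; the p-value is the proportion of
#' permutations (plus one, including the observed arrangement) reaching at
#' least the observed percentage.
#'
#' @inheritParams fit_allometry
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed; results are reproducible given the seed.
#' @return list with `p_value`, `percent_variance` (observed),
#'   `n_permutations`, `seed`.
#' @export
permutation_test <- function(shape_pics, size_pics, n_perm = 10000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  shape_pics <- as.matrix(shape_pics)
  size_pics <- as.numeric(size_pics)
  obs <- fit_allometry(shape_pics, size_pics)$percent_variance
  n <- length(size_pics)
  ss <- sum(size_pics^2)
  tot_ss <- sum(shape_pics^2)
  Yt <- t(shape_pics)  # q x n
  set.seed(as.integer(seed))
  count <- 0L
  chunk <- 2000L
  done <- 0L
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    P <- vapply(seq_len(m), function(i) size_pics[sample.int(n)],
                numeric(n))  # n x m
    cp <- Yt %*% P  # q x m
    pct <- 100 * colSums(cp^2) / ss / tot_ss
    count <- count + sum(pct >= obs * (1 - 1e-12))
    done <- done + m
  }
  list(p_value = (1 + count) / (n_perm + 1),
       percent_variance = obs,
       n_permutations = as.integer(n_perm),
       seed = as.integer(seed))
}

#' Size-correct species-level shape data
#'
#' Removes the allometric component from species-level tangent coordinates
#' using slopes estimated on contrasts: residual_i = shape_i -
#' b (log_size_i - mean log size). Centering the size term preserves the
#' sample mean shape. This is the standard two-step phylogenetic size
#' correction: slopes from contrasts, correction applied to the original
#' species data.
#'
#' @param tangent_coords N x q species-level shape matrix.
#' @param log_sizes length-N vector of log centroid sizes.
#' @param coefficients slope vector from [fit_allometry()].
#' @return N x q matrix of size-corrected shape residuals (same dimnames).
#' @export
size_correct <- function(tangent_coords, log_sizes, coefficients) {
  X <- as.matrix(tangent_coords)
  s <- as.numeric(log_sizes) - mean(log_sizes)
  if (length(s) != nrow(X)) stop("sizes must match shape rows")
  R <- X - outer(s, as.numeric(coefficients))
  dimnames(R) <- dimnames(X)
  R
}
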