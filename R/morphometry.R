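#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks to their
#' centroid -- the standard size measure in geometric morphometrics. It is
#' invariant to rotation and translation and scales linearly with isotropic
#' scaling.
#'
#' @param points k x 2 coordinate matrix.
#' @return a non-negative scalar.
#' @export
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # sqrt(2)
centroid_size <- function(points) {
  points <- as.matrix(points)
  ctr <- colMeans(points)
  sqrt(sum(sweep(points, 2, ctr)^2))
}

# center at origin and scale to unit centroid size
normalize_config <- function(points) {
  ctr <- colMeans(points)
  pts <- sweep(points, 2, ctr)
  cs <- sqrt(sum(pts^2))
  if (cs <= 0) stop("degenerate configuration: zero centroid size")
  pts / cs
}

# optimal rotation (det +1) carrying A onto B in least squares
rotation_to <- function(A, B) {
  sv <- svd(crossprod(A, B))
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {
    u <- sv$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(sv$v)
  }
  R
}

# full ordinary Procrustes distance between two configurations
# (center, unit-scale, optimal rotation)
procrustes_distance <- function(A, B) {
  A <- normalize_config(A)
  B <- normalize_config(B)
  A <- A %*% rotation_to(A, B)
  sqrt(sum((A - B)^2))
}

# deterministic orientation: consensus principal axes to coordinate axes,
# largest-spread axis along +x, landmark 1 at negative y (180-degree flip
# if needed; proper rotations only, so shape is untouched)
orient_sample <- function(shapes, mean_shape) {
  ev <- eigen(stats::cov(mean_shape), symmetric = TRUE)
  R <- ev$vectors
  if (det(R) < 0) R[, 2] <- -R[, 2]
  m <- mean_shape %*% R
  if (m[1, 2] > 0) R <- -R   # 180-degree rotation
  for (i in seq_len(dim(shapes)[1]))
    shapes[i, , ] <- shapes[i, , ] %*% R
  list(shapes = shapes, mean_shape = mean_shape %*% R)
}

sample_mean_shape <- function(shapes) {
  m <- apply(shapes, c(2, 3), mean)
  normalize_config(m)
}

#' Generalized Procrustes Analysis
#'
#' Iterative superimposition: every configuration is centered, scaled to unit
#' centroid size, and rotated to the current consensus; the consensus is the
#' re-standardized arithmetic mean, updated until it stops changing. The
#' consensus orientation is then fixed by a principal-axis convention
#' (largest-spread axis along +x, landmark 1 at negative y) so results are
#' deterministic and invariant to similarity transforms of the inputs.
#'
#' @param configs list of configurations (each with `specimen_id` and
#'   `points`), or a list of k x 2 matrices.
#' @param max_iter maximum consensus updates.
#' @param tol convergence tolerance on the consensus root-sum-of-squares
#'   change.
#' @param region optional region label carried in the result.
#' @return an `aligned_sample`: list with `shapes` (N x k x 2 array),
#'   `centroid_sizes`, `mean_shape`, `tangent_coords` (N x 2k, see
#'   [tangent_project()]), `specimen_ids`, `region`.
#' @export
gpa_align <- function(configs, max_iter = 100L, tol = 1e-10, region = NA_character_) {
  if (length(configs) < 2L) stop("need at least 2 configurations")
  pts <- lapply(configs, function(cf) if (is.list(cf)) cf$points else cf)
  ids <- vapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    if (is.list(cf) && !is.null(cf$specimen_id)) as.character(cf$specimen_id)
    else paste0("spec", i)
  }, character(1))
  k <- nrow(pts[[1]])
  if (any(vapply(pts, nrow, integer(1)) != k))
    stop("all configurations must have the same landmark count")
  N <- length(pts)
  cs <- vapply(pts, centroid_size, numeric(1))
  shapes <- array(NA_real_, c(N, k, 2))
  for (i in seq_len(N)) shapes[i, , ] <- normalize_config(pts[[i]])
  if (k >= 3) {
    sing <- vapply(seq_len(N), function(i)
      svd(shapes[i, , ])$d[2] < 1e-12, logical(1))
    if (any(sing)) stop("degenerate (collinear) configuration: ",
                        paste(ids[sing], collapse = ", "))
  }
  consensus <- shapes[1, , ]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (i in seq_len(N))
      shapes[i, , ] <- shapes[i, , ] %*% rotation_to(shapes[i, , ], consensus)
    new_consensus <- sample_mean_shape(shapes)
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  for (i in seq_len(N))
    shapes[i, , ] <- shapes[i, , ] %*% rotation_to(shapes[i, , ], consensus)
  ori <- orient_sample(shapes, consensus)
  out <- list(shapes = ori$shapes, centroid_sizes = cs,
              mean_shape = ori$mean_shape, specimen_ids = ids,
              region = region)
  out$tangent_coords <- tangent_project(out)
  class(out) <- "aligned_sample"
  out
}

flatten_shapes <- function(shapes) {
  N <- dim(shapes)[1]; k <- dim(shapes)[2]
  out <- matrix(NA_real_, N, 2 * k)
  for (i in seq_len(N)) out[i, ] <- as.vector(t(shapes[i, , ]))
  out  # x1, y1, x2, y2, ...
}

unflatten_shape <- function(v) {
  matrix(v, ncol = 2, byrow = TRUE)
}

#' Orthogonal projection into the tangent space at the mean shape
#'
#' Aligned shapes live on the unit sphere of centered configurations; for
#' statistics they are projected orthogonally onto the plane tangent to that
#' sphere at the mean shape. The projection is idempotent, and the mean
#' shape projects to itself.
#'
#' @param sample an `aligned_sample` from [gpa_align()].
#' @return N x 2k matrix of tangent coordinates (interleaved x1, y1, ...),
#'   rows named by specimen id.
#' @export
tangent_project <- function(sample) {
  m <- as.vector(t(sample$mean_shape))
  m <- m / sqrt(sum(m^2))
  Z <- flatten_shapes(sample$shapes)
  # t_i = m + (I - mm') z_i = z_i - ((z_i . m) - 1) m
  Tn <- Z - outer(as.vector(Z %*% m) - 1, m)
  rownames(Tn) <- sample$specimen_ids
  Tn
}

#' Mean squared Procrustes distance (shape disparity)
#'
#' The mean over specimens of the squared tangent-space distance to the
#' sample mean shape -- the disparity measure used to compare how diverse
#' different skull regions are.
#'
#' @param sample an `aligned_sample`, or an N x q tangent-coordinate matrix.
#' @return a non-negative scalar.
#' @export
mean_sq_procrustes_distance <- function(sample) {
  X <- if (is.matrix(sample)) sample else sample$tangent_coords
  if (nrow(X) < 2L) stop("need at least 2 specimens")
  dev <- sweep(X, 2, colMeans(X))
  mean(rowSums(dev^2))
}

#' Thin-plate-spline bending-energy matrix
#'
#' The k x k upper-left block of the inverse TPS system matrix for a 2D
#' reference configuration: symmetric, positive semi-definite, and
#' annihilating affine displacements (its rows sum to zero and are orthogonal
#' to the reference x and y coordinates). The quadratic form x' B x measures
#' the bending energy of a displacement field sampled at the landmarks.
#'
#' @param reference k x 2 reference configuration, k >= 4, not collinear.
#' @return k x k bending-energy matrix.
#' @export
bending_energy_matrix <- function(reference) {
  X <- as.matrix(reference)
  k <- nrow(X)
  if (k < 4L) stop("need at least 4 reference points")
  D2 <- as.matrix(stats::dist(X))^2
  K <- ifelse(D2 == 0, 0, D2 * log(D2))
  Q <- cbind(1, X)
  if (qr(Q)$rank < 3L) stop("degenerate (collinear) reference configuration")
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Li <- tryCatch(solve(L), error = function(e)
    stop("degenerate reference configuration: TPS system is singular"))
  B <- Li[seq_len(k), seq_len(k), drop = FALSE]
  (B + t(B)) / 2
}

bending_energy <- function(B, shape) {
  sum(diag(t(shape) %*% B %*% shape))
}

# one sliding pass: minimize bending energy w.r.t. the reference by moving
# each semi-landmark along its tangent (chord between curve neighbors)
slide_one <- function(points, B, semi_idx, neighbors) {
  m <- length(semi_idx)
  Tdir <- matrix(NA_real_, m, 2)
  for (i in seq_len(m)) {
    nb <- neighbors[[as.character(semi_idx[i])]]
    chord <- points[nb[2], ] - points[nb[1], ]
    len <- sqrt(sum(chord^2))
    if (len < 1e-12) stop("zero-length tangent: coincident curve neighbors")
    Tdir[i, ] <- chord / len
  }
  S <- matrix(0, nrow(points), m)
  S[cbind(semi_idx, seq_len(m))] <- 1
  A <- matrix(0, m, m); b <- numeric(m)
  for (d in 1:2) {
    Dd <- S %*% diag(Tdir[, d], m)
    A <- A + crossprod(Dd, B %*% Dd)
    b <- b - crossprod(Dd, B %*% points[, d])
  }
  u <- tryCatch(solve(A, b), error = function(e)
    qr.coef(qr(A, tol = 1e-12), b))
  u[is.na(u)] <- 0
  disp <- S %*% (Tdir * as.vector(u))
  points + disp
}

#' Slide semi-landmarks by minimizing bending energy
#'
#' Alternates (i) displacing each specimen's semi-landmarks along their
#' tangent directions (the chord between curve neighbors) to minimize the
#' thin-plate-spline bending energy relative to the current sample mean
#' shape, and (ii) re-superimposing the sample by GPA, until the total
#' bending energy stops changing. Fixed landmarks never move; each sliding
#' step solves a small quadratic program exactly, so bending energy relative
#' to the current reference never increases.
#'
#' @param sample an `aligned_sample` from [gpa_align()].
#' @param template a `shape_template` supplying `semi_idx` and `curves`.
#' @param max_iter outer slide/re-align iterations.
#' @param tol convergence tolerance on the relative change in summed bending
#'   energy.
#' @return an `aligned_sample` with slid, re-aligned shapes; attribute
#'   `"energy_trace"` holds the summed bending energy after each pass.
#' @export
slide_semilandmarks <- function(sample, template, max_iter = 5L, tol = 1e-6) {
  semi_idx <- template$semi_idx
  if (!length(semi_idx)) return(sample)
  neighbors <- semi_neighbors(template$curves, semi_idx)
  shapes <- sample$shapes
  N <- dim(shapes)[1]
  energy_trace <- numeric(0)
  prev_energy <- Inf
  for (it in seq_len(max_iter)) {
    ref <- sample_mean_shape(shapes)
    B <- bending_energy_matrix(ref)
    total <- 0
    for (i in seq_len(N)) {
      slid <- slide_one(shapes[i, , ], B, semi_idx, neighbors)
      e_new <- bending_energy(B, sweep(slid, 2, colMeans(slid)))
      shapes[i, , ] <- slid
      total <- total + e_new
    }
    # re-superimpose after sliding
    cfgs <- lapply(seq_len(N), function(i)
      list(specimen_id = sample$specimen_ids[i], points = shapes[i, , ]))
    re <- gpa_align(cfgs, region = sample$region)
    shapes <- re$shapes
    energy_trace <- c(energy_trace, total)
    if (is.finite(prev_energy) &&
        abs(prev_energy - total) <= tol * max(prev_energy, 1e-300)) break
    prev_energy <- total
  }
  out <- re
  out$centroid_sizes <- sample$centroid_sizes  # sizes are pre-slide, physical
  out$tangent_coords <- tangent_project(out)
  attr(out, "energy_trace") <- energy_trace
  out
}
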