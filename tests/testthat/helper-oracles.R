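# Independent oracles used to check the package's fast implementations.
# Each one takes a deliberately different route (brute force, dense linear
# algebra, or numeric optimization) from the code path it validates.

# ordinary Procrustes distance by brute-force search over the rotation angle
oracle_procrustes_distance <- function(A, B) {
  norm2 <- function(P) {
    P <- sweep(P, 2, colMeans(P))
    P / sqrt(sum(P^2))
  }
  A <- norm2(A); B <- norm2(B)
  d_at <- function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sqrt(sum((A %*% R - B)^2))
  }
  grid <- seq(0, 2 * pi, length.out = 2000)
  th0 <- grid[which.min(vapply(grid, d_at, numeric(1)))]
  opt <- stats::optimize(d_at, c(th0 - 0.01, th0 + 0.01), tol = 1e-14)
  opt$objective
}

# independent contrasts by direct recursion over the tree structure
oracle_pic <- function(tree, x) {
  x <- x[tree$tip.label]
  N <- ape::Ntip(tree)
  edge <- tree$edge; el <- tree$edge.length
  val <- numeric(N + tree$Nnode); val[seq_len(N)] <- x
  extra <- numeric(N + tree$Nnode)
  contrasts <- c()
  rec <- function(node) {
    if (node <= N) return(invisible(NULL))
    kids <- edge[edge[, 1] == node, 2]
    for (kid in kids) rec(kid)
    b <- el[match(kids, edge[, 2])] + extra[kids]
    stopifnot(length(kids) == 2)
    cst <- (val[kids[1]] - val[kids[2]]) / sqrt(sum(b))
    contrasts[as.character(node)] <<- cst
    val[node] <<- (val[kids[1]] / b[1] + val[kids[2]] / b[2]) / (1 / b[1] + 1 / b[2])
    extra[node] <<- prod(b) / sum(b)
    invisible(NULL)
  }
  rec(N + 1L)
  contrasts
}

# ancestral states by numeric minimization of the weighted sum of squared
# changes over all internal-node states
oracle_ancestral <- function(tree, x) {
  x <- x[tree$tip.label]
  N <- ape::Ntip(tree)
  edge <- tree$edge; el <- tree$edge.length
  obj <- function(v) {
    states <- c(x, v)
    sum((states[edge[, 1]] - states[edge[, 2]])^2 / el)
  }
  start <- rep(mean(x), tree$Nnode)
  o <- stats::optim(start, obj, method = "BFGS",
                    control = list(reltol = 1e-16, maxit = 5000))
  stats::setNames(o$par, N + seq_len(tree$Nnode))
}

# pooled-rate multivariate likelihood by dense stacked-normal numeric ML:
# maximizes over per-trait root states and the shared rate directly on the
# Np-dimensional Gaussian density
oracle_pooled_loglik <- function(X, V) {
  N <- nrow(X); p <- ncol(X)
  dens <- function(a, log_s2) {
    s2 <- exp(log_s2)
    Sig <- s2 * V
    Si <- solve(Sig)
    ld <- determinant(Sig, logarithm = TRUE)$modulus
    ll <- 0
    for (j in seq_len(p)) {
      r <- X[, j] - a[j]
      ll <- ll - 0.5 * (N * log(2 * pi) + ld + drop(t(r) %*% Si %*% r))
    }
    as.numeric(ll)
  }
  start <- c(colMeans(X), log(stats::var(as.vector(X)) + 1e-12))
  o <- stats::optim(start, function(th) -dens(th[seq_len(p)], th[p + 1]),
                    method = "BFGS",
                    control = list(reltol = 1e-16, maxit = 10000))
  -o$value
}

# univariate BM ML rate through plain dense GLS formulas
oracle_bm_rate <- function(tree, x) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  Ci <- solve(C)
  one <- rep(1, length(x))
  a <- drop(t(one) %*% Ci %*% x) / drop(t(one) %*% Ci %*% one)
  r <- x - a
  drop(t(r) %*% Ci %*% r) / length(x)
}

# small fixed trees used across tests
two_tip_tree <- function(b = 1) ape::read.tree(text = sprintf("(A:%g,B:%g);", b, b))
three_tip_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# random non-degenerate k-point configuration
random_config <- function(k, seed) {
  set.seed(seed)
  matrix(stats::rnorm(2 * k), k, 2)
}
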