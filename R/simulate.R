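#' Simulate a pure-birth time-calibrated phylogeny
#'
#' A Yule (pure-birth) tree with the requested number of tips: rooted,
#' ultrametric, fully bifurcating, with strictly positive branch lengths.
#' Reproducible from the seed.
#'
#' @param n_tips number of tips (>= 3).
#' @param birth_rate speciation rate per unit time (> 0).
#' @param seed integer seed.
#' @return an `ape::phylo` tree with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  if (n_tips < 3L) stop("n_tips must be >= 3")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  set.seed(as.integer(seed))
  ape::rphylo(n_tips, birth = birth_rate, death = 0)
}

#' Simulate multivariate trait evolution on a tree
#'
#' Draws p independent traits from the multivariate normal implied by the
#' chosen model's tree transformation: among-species covariance
#' `sigma2 * V(model, params)` (see [transform_covariance()]) and zero mean
#' (for OU-type models the optimum is the origin, i.e. the template shape).
#'
#' @param tree a rooted `ape::phylo` tree (ultrametric for OU models).
#' @param p number of traits.
#' @param model one of `"BM"`, `"OU"`, `"EB"`, `"delta"`, `"delta_OU"`.
#' @param params named list with `sigma2` (> 0, default 1) plus the model's
#'   shape parameters (`alpha`, `delta`, `r`).
#' @param seed integer seed.
#' @return N x p matrix of tip values, rows named by tip label.
#' @export
simulate_traits <- function(tree, p, model = "BM", params = list(sigma2 = 1),
                            seed = 1L) {
  if (p < 1L) stop("p must be >= 1")
  sigma2 <- if (is.null(params$sigma2)) 1 else params$sigma2
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  V <- sigma2 * transform_covariance(tree, model, params)
  U <- chol(V)
  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(nrow(V) * p), nrow(V), p)
  X <- crossprod(U, Z)
  rownames(X) <- rownames(V)
  colnames(X) <- paste0("trait", seq_len(p))
  X
}

#' Orthonormal basis of the shape tangent space at a template
#'
#' Columns span the orthogonal complement, within the 2k-dimensional
#' coordinate space, of the four similarity directions at the normalized
#' template (x/y translation, rotation, scaling). Trait deviations mapped
#' through this basis therefore live exactly in shape space and are
#' recoverable by Procrustes superimposition.
#'
#' @param template_points k x 2 template coordinates.
#' @return 2k x (2k-4) orthonormal matrix (coordinates interleaved
#'   x1, y1, x2, y2, ...).
#' @export
tangent_basis <- function(template_points) {
  tn <- normalize_config(template_points)
  k <- nrow(tn)
  tvec <- as.vector(t(tn))
  rot <- as.vector(t(cbind(-tn[, 2], tn[, 1])))
  tr_x <- rep(c(1, 0), k); tr_y <- rep(c(0, 1), k)
  Cns <- cbind(tr_x, tr_y, tvec, rot)
  qr_full <- qr(cbind(Cns, diag(2 * k)))
  Q <- qr.Q(qr_full)
  B <- Q[, (ncol(Cns) + 1):(2 * k), drop = FALSE]
  B
}

#' Map simulated traits onto landmark configurations
#'
#' Converts a species x p trait matrix into raw 2D landmark configurations:
#' each species' traits displace the normalized template along the first p
#' orthonormal tangent-basis directions; an optional allometric shape
#' component proportional to centered log size is injected along the
#' (p+1)-th basis direction, scaled so it accounts for `allometry_fraction`
#' of the total shape variance; independent Gaussian digitization noise is
#' added per coordinate; and each configuration is then given a random
#' rotation, translation, and digitizer scale to emulate raw photographs.
#'
#' @param traits N x p matrix with species rownames.
#' @param template a `shape_template`.
#' @param allometry_fraction proportion of shape variance that is
#'   size-related, in [0, 1).
#' @param noise_sd digitization noise standard deviation, in units of the
#'   normalized (unit-centroid-size) template.
#' @param seed integer seed.
#' @param log_size_sd standard deviation of species log centroid sizes
#'   (tip-level standard deviation).
#' @param tree optional `ape::phylo` tree over the trait rownames; when
#'   supplied, log centroid sizes evolve by Brownian motion on the tree
#'   (rate chosen so the expected tip variance is `log_size_sd^2`), the
#'   realistic situation for body size; otherwise sizes are drawn iid.
#' @return list with `configs` (list of configurations with `specimen_id`,
#'   `points`, `scale`), `log_sizes` (named vector of true log centroid
#'   sizes), `allometry_vector` (the injected tangent direction, or NULL).
#' @export
traits_to_landmarks <- function(traits, template, allometry_fraction = 0,
                                noise_sd = 0, seed = 1L, log_size_sd = 0.6,
                                tree = NULL) {
  traits <- as.matrix(traits)
  k <- nrow(template$points)
  p <- ncol(traits)
  max_p <- 2 * k - 4 - (allometry_fraction > 0)
  if (p > max_p)
    stop("p too large for this template: at most ", max_p, " trait dimensions")
  if (allometry_fraction < 0 || allometry_fraction >= 1)
    stop("allometry_fraction must be in [0, 1)")
  N <- nrow(traits)
  tn <- normalize_config(template$points)
  B <- tangent_basis(template$points)
  dev <- traits %*% t(B[, seq_len(p), drop = FALSE])  # N x 2k
  set.seed(as.integer(seed))
  if (is.null(tree)) {
    log_sizes <- stats::rnorm(N, 0, log_size_sd)
    names(log_sizes) <- rownames(traits)
  } else {
    C <- phylo_covariance(tree)
    rate <- log_size_sd^2 / mean(diag(C))
    ls <- crossprod(chol(rate * C), stats::rnorm(nrow(C)))
    log_sizes <- stats::setNames(as.vector(ls), rownames(C))[rownames(traits)]
  }
  a_vec <- NULL
  if (allometry_fraction > 0) {
    a_vec <- B[, p + 1]
    s_c <- log_sizes - mean(log_sizes)
    v_dev <- sum(apply(dev, 2, stats::var))
    v_s <- stats::var(s_c)
    cc <- if (v_s > 0 && v_dev > 0)
      sqrt(allometry_fraction / (1 - allometry_fraction) * v_dev / v_s) else 0
    dev <- dev + outer(s_c * cc, a_vec)
  }
  if (noise_sd > 0)
    dev <- dev + matrix(stats::rnorm(N * 2 * k, 0, noise_sd), N, 2 * k)
  cs_template <- centroid_size(template$points)
  configs <- vector("list", N)
  for (i in seq_len(N)) {
    shp <- tn + unflatten_shape(dev[i, ])
    phys <- shp * cs_template * exp(log_sizes[i])
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    phys <- phys %*% R
    phys <- sweep(phys, 2, stats::runif(2, -5, 5), "+")
    scale <- stats::runif(1, 0.005, 0.05)
    configs[[i]] <- list(specimen_id = rownames(traits)[i],
                         points = phys, scale = scale)
  }
  list(configs = configs, log_sizes = log_sizes, allometry_vector = a_vec)
}

#' Simulate a complete synthetic skull dataset
#'
#' Convenience wrapper tying the generator together: a pure-birth tree, one
#' trait matrix per requested group simulated under the chosen model, raw
#' landmark configurations written through the template, and (optionally)
#' TPS/Newick/ground-truth files on disk.
#'
#' @param n_tips number of species.
#' @param p trait dimensions carrying evolutionary signal per group (capped
#'   at each template's shape-space dimension, 2k-4, minus one when an
#'   allometric direction is injected).
#' @param model,params generating model, as [simulate_traits()];
#'   `params$sigma2` may be a named vector giving one rate per group.
#' @param template_names named character vector: group name -> template name.
#' @param allometry_fraction,noise_sd,log_size_sd as
#'   [traits_to_landmarks()].
#' @param birth_rate pure-birth speciation rate.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param dir if non-NULL, writes `<group>.tps`, `tree.nwk` and
#'   `truth.txt` (flat key=value ground-truth sidecar) there.
#' @return list with `tree`, per-group `groups` (each: `traits`, `configs`,
#'   `log_sizes`), and `truth` (named list of generating parameters).
#' @export
simulate_skull_dataset <- function(n_tips = 100L, p = 20L, model = "BM",
                                   params = list(sigma2 = 5e-4),
                                   template_names = c(cranium = "cranium19"),
                                   allometry_fraction = 0.03,
                                   noise_sd = 0.005,
                                   log_size_sd = 0.6,
                                   birth_rate = 1,
                                   seed = 1L, dir = NULL) {
  seed <- as.integer(seed)
  tree <- simulate_tree(n_tips, birth_rate, seed = seed)
  sig <- params$sigma2
  if (is.null(sig)) sig <- 2e-3
  if (length(sig) == 1L && length(template_names) > 1L)
    sig <- stats::setNames(rep(sig, length(template_names)),
                           names(template_names))
  groups <- list()
  for (gi in seq_along(template_names)) {
    g <- names(template_names)[gi]
    tpl <- shape_template(template_names[[gi]])
    pars_g <- params
    pars_g$sigma2 <- if (length(template_names) > 1L) sig[[g]] else sig[[1]]
    # cap the signal dimension at the template's shape-space size
    p_g <- min(p, 2L * nrow(tpl$points) - 4L - (allometry_fraction > 0))
    traits <- simulate_traits(tree, p_g, model, pars_g,
                              seed = seed + 1000L * gi)
    lm <- traits_to_landmarks(traits, tpl, allometry_fraction, noise_sd,
                              seed = seed + 1000L * gi + 500L,
                              log_size_sd = log_size_sd, tree = tree)
    groups[[g]] <- list(template = tpl, traits = traits,
                        configs = lm$configs, log_sizes = lm$log_sizes)
  }
  truth <- c(list(n_tips = n_tips, p = p, model = model,
                  allometry_fraction = allometry_fraction,
                  noise_sd = noise_sd, log_size_sd = log_size_sd,
                  birth_rate = birth_rate, seed = seed),
             stats::setNames(as.list(sig), paste0("sigma2_", names(template_names))),
             params[setdiff(names(params), "sigma2")])
  out <- list(tree = tree, groups = groups, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (g in names(groups))
      write_tps(groups[[g]]$configs, file.path(dir, paste0(g, ".tps")))
    writeLines(write_newick(tree), file.path(dir, "tree.nwk"))
    writeLines(paste0(names(truth), "=",
                      vapply(truth, function(v) paste(format(v, digits = 12),
                                                      collapse = ","),
                             character(1))),
               file.path(dir, "truth.txt"))
  }
  out
}
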