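# covariance transforms, pooled likelihood, model fitting and selection

test_that("covariance transforms: neutral parameters return C exactly", {
  tr <- simulate_tree(25, 1, seed = 71)
  C <- phylo_covariance(tr)
  expect_equal(transform_covariance(tr, "delta", list(delta = 1)), C)
  expect_equal(transform_covariance(tr, "EB", list(r = 0)), C)
  V <- transform_covariance(tr, "OU", list(alpha = 1e-8))
  expect_lt(max(abs(V - C)) / max(C), 1e-5)
  expect_error(transform_covariance(tr, "delta", list(delta = -1)), "delta")
  nonu <- parse_newick("((A:1,B:2):1,C:4);")
  expect_error(transform_covariance(nonu, "OU", list(alpha = 1)), "ultrametric")
})

test_that("transformed covariances stay symmetric PSD across the menu", {
  tr <- simulate_tree(40, 1, seed = 72)
  Td <- max(ape::node.depth.edgelength(tr))
  cases <- list(list("delta", list(delta = 0.3)),
                list("delta", list(delta = 2.6)),
                list("EB", list(r = -2 / Td)),
                list("OU", list(alpha = 4 / Td)),
                list("delta_OU", list(delta = 2, alpha = 3 / Td)))
  for (cs in cases) {
    V <- transform_covariance(tr, cs[[1]], cs[[2]])
    expect_lt(max(abs(V - t(V))), 1e-12)
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * sum(diag(V)))
  }
})

test_that("pooled log-likelihood matches a dense numeric-ML oracle", {
  tr <- simulate_tree(8, 1, seed = 73)
  X <- simulate_traits(tr, 2, "BM", list(sigma2 = 0.7), seed = 74)
  ll <- pooled_loglik(X, tr, "BM")
  V <- phylo_covariance(tr)
  ll_oracle <- oracle_pooled_loglik(X[rownames(V), ], V)
  expect_equal(as.numeric(ll), ll_oracle, tolerance = 1e-6)

  # p = 1 reduces to standard univariate phylogenetic ML
  x1 <- X[, 1, drop = FALSE]
  ll1 <- pooled_loglik(x1, tr, "BM")
  expect_equal(as.numeric(ll1), oracle_pooled_loglik(x1[rownames(V), , drop = FALSE], V),
               tolerance = 1e-6)

  # duplicating a trait column is reproduced by the oracle too
  X2 <- cbind(X[, 1, drop = FALSE], X[, 1, drop = FALSE])
  colnames(X2) <- c("a", "b")
  ll2 <- pooled_loglik(X2, tr, "BM")
  expect_equal(as.numeric(ll2),
               oracle_pooled_loglik(X2[rownames(V), ], V), tolerance = 1e-6)

  # data constant at the root vector: degenerate zero rate is flagged
  Xc <- matrix(5, ape::Ntip(tr), 2,
               dimnames = list(tr$tip.label, c("a", "b")))
  expect_error(pooled_loglik(Xc, tr, "BM"), "degenerate|zero")
})

test_that("model nesting: delta(1) and EB(0) equal BM, OU approaches it", {
  tr <- simulate_tree(30, 1, seed = 75)
  X <- simulate_traits(tr, 4, "delta", list(sigma2 = 1, delta = 1.7), seed = 76)
  llb <- as.numeric(pooled_loglik(X, tr, "BM"))
  expect_equal(as.numeric(pooled_loglik(X, tr, "delta", list(delta = 1))), llb,
               tolerance = 1e-8)
  expect_equal(as.numeric(pooled_loglik(X, tr, "EB", list(r = 0))), llb,
               tolerance = 1e-8)
  expect_equal(as.numeric(pooled_loglik(X, tr, "OU", list(alpha = 1e-9))), llb,
               tolerance = 1e-4)
})

test_that("sigma2_mult: univariate GLS oracle and rate-time trade-off", {
  tr <- simulate_tree(15, 1, seed = 77)
  x <- simulate_traits(tr, 1, "BM", list(sigma2 = 3), seed = 78)
  expect_equal(sigma_mult(x, tr), oracle_bm_rate(tr, x[, 1]),
               tolerance = 1e-10)
  tr2 <- tr; tr2$edge.length <- 2 * tr$edge.length
  expect_equal(sigma_mult(x, tr2), sigma_mult(x, tr) / 2, tolerance = 1e-10)
})

test_that("AIC bookkeeping and parsimony tie-break", {
  tr <- simulate_tree(20, 1, seed = 79)
  X <- simulate_traits(tr, 3, "BM", list(sigma2 = 1), seed = 80)
  fb <- fit_model(X, tr, "BM")
  expect_equal(fb$aic, 2 * 2 - 2 * fb$loglik)
  fd <- fit_model(X, tr, "delta")
  expect_equal(fd$n_params, 3L)
  mk <- function(model, aic, np) structure(
    list(model = model, aic = aic, n_params = as.integer(np),
         loglik = (2 * np - aic) / 2), class = "evo_model_fit")
  sel <- select_model(list(mk("a", 10, 3), mk("b", 12, 3), mk("c", 9, 4)))
  expect_equal(sel$best$model, "c")
  sel2 <- select_model(list(mk("BM", 10, 2), mk("OU", 10, 3)))
  expect_equal(sel2$best$model, "BM")
})

test_that("fitted likelihood at the neutral point equals the BM fit", {
  tr <- simulate_tree(30, 1, seed = 81)
  X <- simulate_traits(tr, 5, "BM", list(sigma2 = 0.4), seed = 82)
  llb <- fit_model(X, tr, "BM")$loglik
  lld <- as.numeric(pooled_loglik(X, tr, "delta", list(delta = 1)))
  expect_equal(lld, llb, tolerance = 1e-8)
  fd <- fit_model(X, tr, "delta")
  expect_gte(fd$loglik, llb - 1e-6)  # delta nests BM
  fdo <- fit_model(X, tr, "delta_OU")
  expect_gte(fdo$loglik, llb - 1e-4)
})
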