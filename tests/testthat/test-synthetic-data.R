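# synthetic-data generator: trees, traits, landmark mapping, TPS files

test_that("pure-birth trees are ultrametric, bifurcating and reproducible", {
  tr <- simulate_tree(3, 1.0, seed = 1)
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(tr$Nnode, 2)
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_lt(diff(range(depths)), 1e-10 * max(depths))

  t1 <- simulate_tree(50, 1.0, seed = 7)
  t2 <- simulate_tree(50, 1.0, seed = 7)
  expect_identical(write_newick(t1), write_newick(t2))

  t3 <- simulate_tree(200, 0.5, seed = 3)
  expect_equal(nrow(t3$edge), 2 * 200 - 2)
  expect_true(all(t3$edge.length > 0))
  expect_error(simulate_tree(2, 1, seed = 1), "n_tips")
})

test_that("BM contrast variance on a two-tip tree matches closed form", {
  tr <- two_tip_tree(1)
  d <- vapply(seq_len(2000), function(i) {
    x <- simulate_traits(tr, p = 1, model = "BM", params = list(sigma2 = 1),
                         seed = i)
    x["A", 1] - x["B", 1]
  }, numeric(1))
  # Var(x_A - x_B) = sigma2 * (b_A + b_B) = 2
  expect_gt(var(d), 2 - 0.15)
  expect_lt(var(d), 2 + 0.15)
})

test_that("delta = 1 reproduces BM draws exactly at the same seed", {
  tr <- simulate_tree(20, 1, seed = 4)
  a <- simulate_traits(tr, 3, "BM", list(sigma2 = 0.5), seed = 9)
  b <- simulate_traits(tr, 3, "delta", list(sigma2 = 0.5, delta = 1), seed = 9)
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(simulate_traits(tr, 3, "BM", list(sigma2 = -1), seed = 1),
               "sigma2")
})

test_that("OU tip variance approaches the stationary value on a deep tree", {
  tr <- ape::read.tree(text = "((A:49,B:49):1,C:50);")
  x <- simulate_traits(tr, p = 4000, model = "OU",
                       params = list(sigma2 = 1, alpha = 10), seed = 2)
  v <- mean(apply(x, 1, var))
  expect_equal(v, 1 / (2 * 10), tolerance = 0.1)
})

test_that("model covariances degenerate to BM at the neutral parameters", {
  tr <- simulate_tree(30, 1, seed = 11)
  C <- transform_covariance(tr, "BM")
  expect_lt(max(abs(transform_covariance(tr, "delta", list(delta = 1)) - C)), 1e-8)
  expect_lt(max(abs(transform_covariance(tr, "EB", list(r = 0)) - C)), 1e-8)
  V <- transform_covariance(tr, "OU", list(alpha = 1e-8))
  expect_lt(max(abs(V - C)) / max(C), 1e-5)
  Vdo <- transform_covariance(tr, "delta_OU", list(delta = 1, alpha = 1e-8))
  expect_lt(max(abs(Vdo - C)) / max(C), 1e-5)
})

test_that("zero traits map to similarity copies of the template", {
  tpl <- shape_template("cranium19")
  traits <- matrix(0, 8, 5, dimnames = list(paste0("s", 1:8), NULL))
  lm <- traits_to_landmarks(traits, tpl, allometry_fraction = 0,
                            noise_sd = 0, seed = 3)
  for (cf in lm$configs)  # tolerance limited by the oracle's angular search
    expect_lt(oracle_procrustes_distance(cf$points, tpl$points), 1e-6)
  # reproducibility straight through to the TPS file
  f1 <- tempfile(fileext = ".tps"); f2 <- tempfile(fileext = ".tps")
  lm2 <- traits_to_landmarks(traits, tpl, 0, 0, seed = 3)
  write_tps(lm$configs, f1); write_tps(lm2$configs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("trait dimension is capped by the template's shape space", {
  tpl <- shape_template("mandible10")  # 2k - 4 = 16
  traits <- matrix(0, 5, 17, dimnames = list(paste0("s", 1:5), NULL))
  expect_error(traits_to_landmarks(traits, tpl, 0, 0, seed = 1), "too large")
})

test_that("tangent basis is orthonormal and kills similarity directions", {
  tpl <- shape_template("cranium19")
  B <- tangent_basis(tpl$points)
  expect_equal(dim(B), c(38, 34))
  expect_equal(crossprod(B), diag(34), tolerance = 1e-10)
  tn <- morpholab:::normalize_config(tpl$points)
  tvec <- as.vector(t(tn))
  rot <- as.vector(t(cbind(-tn[, 2], tn[, 1])))
  for (v in list(rep(c(1, 0), 19), rep(c(0, 1), 19), tvec, rot))
    expect_lt(max(abs(crossprod(B, v))), 1e-10)
})

test_that("injected allometric signal is recovered by the allometry test", {
  tpl <- shape_template("cranium19")
  tr <- simulate_tree(100, 1, seed = 21)
  traits <- simulate_traits(tr, 6, "BM", list(sigma2 = 2e-3), seed = 22)
  lm <- traits_to_landmarks(traits, tpl, allometry_fraction = 0.5,
                            noise_sd = 0.002, seed = 23)
  al <- gpa_align(lm$configs)
  pics <- pic_matrix(tr, al$tangent_coords)
  lcs <- log(al$centroid_sizes); names(lcs) <- al$specimen_ids
  spic <- pic_matrix(tr, matrix(lcs, ncol = 1, dimnames = list(names(lcs), "s")))
  pt <- permutation_test(pics$contrasts, spic$contrasts[, 1],
                         n_perm = 499, seed = 5)
  expect_lt(pt$p_value, 0.05)
  expect_gt(pt$percent_variance, 10)
})
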