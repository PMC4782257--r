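# GPA, bending energy, semi-landmark sliding, tangent space, disparity

test_that("centroid size: hand values, homogeneity, degenerate point", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2))
  cfg <- random_config(7, 1)
  expect_equal(centroid_size(2 * cfg), 2 * centroid_size(cfg))
  R <- matrix(c(cos(0.7), sin(0.7), -sin(0.7), cos(0.7)), 2, 2)
  expect_equal(centroid_size(cfg %*% R + 3), centroid_size(cfg))
  expect_equal(centroid_size(matrix(c(2, 5), 1, 2)), 0)
})

test_that("GPA collapses identical and similarity-equivalent configurations", {
  cfg <- random_config(6, 2)
  al <- gpa_align(list(cfg, cfg))
  expect_lt(sqrt(sum((al$shapes[1, , ] - al$shapes[2, , ])^2)), 1e-12)
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  al2 <- gpa_align(list(cfg, cfg %*% R + 10))
  expect_lt(sqrt(sum((al2$shapes[1, , ] - al2$shapes[2, , ])^2)), 1e-10)
})

test_that("GPA output is invariant to similarity transforms of the inputs", {
  cfgs <- lapply(1:5, function(i) random_config(8, i) + 0.3 * random_config(8, 99))
  base <- gpa_align(cfgs)
  set.seed(31)
  jittered <- lapply(cfgs, function(P) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    runif(1, 0.2, 5) * P %*% R + matrix(runif(2, -9, 9), nrow(P), 2, byrow = TRUE)
  })
  again <- gpa_align(jittered)
  expect_lt(max(abs(base$shapes - again$shapes)), 1e-8)
  expect_lt(max(abs(base$mean_shape - again$mean_shape)), 1e-8)
})

test_that("pairwise aligned distances match the brute-force rotation search", {
  shapes <- lapply(1:3, function(i) random_config(4, 20 + i))
  for (i in 1:2) for (j in (i + 1):3) {
    d_oracle <- oracle_procrustes_distance(shapes[[i]], shapes[[j]])
    d_pkg <- morpholab:::procrustes_distance(shapes[[i]], shapes[[j]])
    expect_equal(d_pkg, d_oracle, tolerance = 1e-6)
  }
})

test_that("bending-energy matrix annihilates affine terms and is PSD", {
  ref <- shape_template("cranium19")$points
  B <- bending_energy_matrix(ref)
  expect_lt(max(abs(B %*% rep(1, 19))), 1e-8)
  expect_lt(max(abs(B %*% ref[, 1])), 1e-8)
  expect_lt(max(abs(B %*% ref[, 2])), 1e-8)
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(ev))
  # pure-affine displacement has zero bending energy
  ref5 <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.4, 0.6))
  B5 <- bending_energy_matrix(ref5)
  A <- matrix(c(0.2, -0.1, 0.05, 0.3), 2, 2)
  disp <- ref5 %*% A + 1.5
  expect_lt(abs(morpholab:::bending_energy(B5, disp)), 1e-10)
  expect_error(bending_energy_matrix(cbind(1:5, 2 * (1:5))), "collinear|degenerate")
})

test_that("single free semi-landmark slides to the 1-D quadratic optimum", {
  tpl <- shape_template("cranium19")
  ref <- tpl$points
  B <- bending_energy_matrix(ref)
  nb <- morpholab:::semi_neighbors(tpl$curves, tpl$semi_idx)
  set.seed(7)
  pts <- ref + matrix(rnorm(38, 0, 0.03), 19, 2)
  s <- 16L  # one vault semi-landmark free, all others pinned
  slid <- morpholab:::slide_one(pts, B, s, nb)
  expect_equal(slid[-s, ], pts[-s, ])  # only the free point moves
  chord <- pts[nb[["16"]][2], ] - pts[nb[["16"]][1], ]
  tdir <- chord / sqrt(sum(chord^2))
  energy_at <- function(u) {
    q <- pts; q[s, ] <- pts[s, ] + u * tdir
    morpholab:::bending_energy(B, q)
  }
  grid <- seq(-0.5, 0.5, length.out = 4001)
  u0 <- grid[which.min(vapply(grid, energy_at, numeric(1)))]
  u_star <- stats::optimize(energy_at, c(u0 - 0.001, u0 + 0.001), tol = 1e-14)$minimum
  u_pkg <- sum((slid[s, ] - pts[s, ]) * tdir)
  expect_equal(u_pkg, u_star, tolerance = 1e-6)
})

test_that("sliding is a descent on bending energy and fixes its own optimum", {
  tpl <- shape_template("cranium19")
  set.seed(8)
  cfgs <- lapply(1:12, function(i)
    list(specimen_id = paste0("s", i),
         points = tpl$points + matrix(rnorm(38, 0, 0.02), 19, 2)))
  al <- gpa_align(cfgs)
  ref <- morpholab:::sample_mean_shape(al$shapes)
  B <- bending_energy_matrix(ref)
  pre <- sum(vapply(1:12, function(i)
    morpholab:::bending_energy(B, al$shapes[i, , ]), numeric(1)))
  nb <- morpholab:::semi_neighbors(tpl$curves, tpl$semi_idx)
  post <- sum(vapply(1:12, function(i) {
    q <- morpholab:::slide_one(al$shapes[i, , ], B, tpl$semi_idx, nb)
    morpholab:::bending_energy(B, q)
  }, numeric(1)))
  expect_lte(post, pre + 1e-12)
  slid <- slide_semilandmarks(al, tpl)
  tr <- attr(slid, "energy_trace")
  expect_true(length(tr) >= 1)
  # identical copies of one shape are already at the bending-energy minimum
  # (zero deformation), so sliding is a no-op
  same <- lapply(1:5, function(i)
    list(specimen_id = paste0("c", i), points = tpl$points))
  al_same <- gpa_align(same)
  slid_same <- slide_semilandmarks(al_same, tpl, max_iter = 3)
  expect_lt(max(abs(slid_same$shapes - al_same$shapes)), 1e-8)
})

test_that("tangent projection is idempotent and exact for the mean shape", {
  cfgs <- lapply(1:6, function(i) random_config(7, 40 + i))
  al <- gpa_align(cfgs)
  T1 <- tangent_project(al)
  al2 <- al
  for (i in 1:6) al2$shapes[i, , ] <- morpholab:::unflatten_shape(T1[i, ])
  T2 <- tangent_project(al2)
  expect_equal(T1, T2, tolerance = 1e-12)
  m <- as.vector(t(al$mean_shape))
  alm <- al; alm$shapes <- array(m, c(1, 7, 2))
  alm$shapes[1, , ] <- al$mean_shape
  alm$specimen_ids <- "mean"
  expect_equal(as.vector(tangent_project(alm)), m, tolerance = 1e-12)
})

test_that("tangent and full Procrustes distances agree for small shapes", {
  tpl <- shape_template("mandible10")
  set.seed(55)
  cfgs <- lapply(1:20, function(i)
    list(specimen_id = paste0("s", i),
         points = tpl$points + matrix(rnorm(20, 0, 0.004), 10, 2)))
  al <- gpa_align(cfgs)
  mshape <- al$mean_shape
  for (i in c(1, 7, 13)) {
    d_full <- morpholab:::procrustes_distance(al$shapes[i, , ], mshape)
    d_tan <- sqrt(sum((al$tangent_coords[i, ] - as.vector(t(mshape)) /
                         sqrt(sum(mshape^2)))^2))
    if (d_full < 0.05) expect_equal(d_tan, d_full, tolerance = 0.01 * d_full)
  }
})

test_that("disparity P2: zero, two-point case, permutation invariance", {
  cfgs <- lapply(1:4, function(i) random_config(6, 3))
  al <- gpa_align(cfgs)
  expect_equal(mean_sq_procrustes_distance(al), 0, tolerance = 1e-20)
  X <- rbind(c(0, 0, 0), c(0.2, 0, 0))  # tangent distance d = 0.2
  expect_equal(mean_sq_procrustes_distance(X), 0.2^2 / 4)
  set.seed(9)
  Y <- matrix(rnorm(50), 10, 5)
  expect_equal(mean_sq_procrustes_distance(Y),
               mean_sq_procrustes_distance(Y[sample(10), ]))
})
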