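test_that("G-cross matches the analytic step-function case", {
  g <- gcross_auc(cbind(0, 0), cbind(50, 0), r_max = 150)
  expect_equal(g$auc, (150 - 50) / 150, tolerance = 1e-12)
  expect_true(all(diff(g$cdf) >= 0))
  # coincident targets saturate the CDF immediately
  pts <- random_points(30)
  expect_equal(gcross_auc(pts, pts, r_max = 150)$auc, 1, tolerance = 1e-12)
})

test_that("G-cross equals the brute-force all-pairs oracle", {
  set.seed(61)
  for (i in 1:25) {
    A <- random_points(200); B <- random_points(200)
    g <- gcross_auc(A, B, r_max = 150)
    oracle <- brute_gcross_auc(brute_nn_dist(A, B), r_max = 150)
    expect_equal(g$auc, oracle, tolerance = 1e-12)
    expect_true(all(g$cdf >= 0 & g$cdf <= 1))
  }
  # same-phenotype case excludes self pairs
  A <- random_points(50)
  g <- gcross_auc(A, A, self = TRUE)
  oracle <- brute_gcross_auc(brute_nn_dist(A, A, self = TRUE))
  expect_equal(g$auc, oracle, tolerance = 1e-12)
  expect_lt(g$auc, 1)
})

test_that("empty point sets give null G-cross results", {
  empty <- matrix(numeric(), 0, 2)
  expect_true(is.na(gcross_auc(empty, random_points(10))$auc))
  expect_true(is.na(gcross_auc(random_points(10), empty)$auc))
})

test_that("G-cross is invariant to rigid motions", {
  set.seed(62)
  A <- random_points(80); B <- random_points(80)
  base <- gcross_auc(A, B)$auc
  th <- 0.7; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(gcross_auc(A %*% Rm, B %*% Rm)$auc, base,
               tolerance = 1e-12)
  expect_equal(gcross_auc(sweep(A, 2, c(100, -50)),
                          sweep(B, 2, c(100, -50)))$auc, base,
               tolerance = 1e-12)
})

test_that("alpha-shape edge cells recover lattice and hull boundaries", {
  # 5x5 grid with 1 um spacing: the 16 perimeter cells are the boundary
  g <- expand.grid(x = 0:4, y = 0:4)
  cells <- data.frame(core_id = "c", patient_id = "p",
                      cell_id = paste0("x", 1:25),
                      x_um = g$x, y_um = g$y, cn2_label = "tumor")
  flag <- edge_cells(cells, "cn2_label")
  expect_equal(sum(flag), 16)
  expect_setequal(which(flag),
                  which(g$x %in% c(0, 4) | g$y %in% c(0, 4)))
  # convex cloud with huge alpha reduces to the convex hull vertex set
  set.seed(63)
  pts <- random_points(60)
  cells2 <- data.frame(core_id = "c", patient_id = "p",
                       cell_id = paste0("y", 1:60),
                       x_um = pts[, 1], y_um = pts[, 2],
                       cn2_label = "tumor")
  flag2 <- edge_cells(cells2, "cn2_label", alpha = 1e6)
  expect_setequal(which(flag2), grDevices::chull(pts))
})

test_that("concave boundaries include inner-arc cells the hull misses", {
  # C shape: annulus segment opening to the right
  set.seed(64)
  th <- runif(400, pi / 4, 7 * pi / 4)
  r <- runif(400, 60, 100)
  cells <- data.frame(core_id = "c", patient_id = "p",
                      cell_id = paste0("x", 1:400),
                      x_um = r * cos(th), y_um = r * sin(th),
                      cn2_label = "tumor")
  flag <- edge_cells(cells, "cn2_label")
  hull <- rep(FALSE, 400)
  hull[grDevices::chull(cells$x_um, cells$y_um)] <- TRUE
  inner <- cells$x_um^2 + cells$y_um^2 < 70^2
  # the alpha shape flags inner-arc cells; the convex hull cannot
  expect_gt(sum(flag & inner & !hull), 0)
  expect_equal(sum(hull & inner), 0)
})

test_that("degenerate collinear regions fall back to the convex hull", {
  cells <- data.frame(core_id = "c", patient_id = "p",
                      cell_id = paste0("x", 1:6),
                      x_um = 1:6, y_um = 2 * (1:6), cn2_label = "tumor")
  expect_warning(flag <- edge_cells(cells, "cn2_label"), "degenerate")
  expect_true(any(flag))
})

test_that("JSD satisfies metric properties on point patterns", {
  set.seed(65)
  A <- random_points(100)
  expect_lt(jsd(A, A)$distance, 1e-9)
  B <- random_points(100)
  expect_equal(jsd(A, B)$distance, jsd(B, A)$distance, tolerance = 1e-12)
  d <- jsd(A, B)$distance
  expect_gte(d, 0); expect_lte(d, 1)
  # fewer than 2 points per set is null
  expect_true(is.na(jsd(A[1, , drop = FALSE], B)$distance))
})

test_that("well-separated clusters approach complete separation", {
  set.seed(66)
  A <- cbind(rnorm(80, 0, 10), rnorm(80, 0, 10))
  B <- cbind(rnorm(80, 500, 10), rnorm(80, 0, 10))
  r <- jsd(A, B, bandwidth = 20)
  expect_gte(r$distance, 0.99)
  # numerical-integration oracle on the two normalized kernel intensities
  gx <- seq(-80, 580, length.out = 600)
  gy <- seq(-80, 80, length.out = 200)
  pmf <- function(P) {
    Kx <- dnorm(outer(gx, P[, 1], "-") / 20)
    Ky <- dnorm(outer(P[, 2], gy, "-") / 20)
    z <- Kx %*% Ky; z / sum(z)
  }
  P <- pmf(A); Q <- pmf(B); M <- (P + Q) / 2
  kl <- function(p, m) { nz <- p > 0; sum(p[nz] * log2(p[nz] / m[nz])) }
  oracle <- sqrt(0.5 * kl(P, M) + 0.5 * kl(Q, M))
  expect_equal(r$distance, oracle, tolerance = 0.01)
})

test_that("JSD grows monotonically as clusters separate", {
  set.seed(67)
  A <- cbind(rnorm(60, 0, 15), rnorm(60, 0, 15))
  B0 <- cbind(rnorm(60, 0, 15), rnorm(60, 0, 15))
  dist_at <- vapply(c(0, 50, 100, 200, 400), function(dx)
    jsd(A, sweep(B0, 2, c(-dx, 0)), bandwidth = 20)$distance, numeric(1))
  expect_true(all(diff(dist_at) >= -1e-9))
})

test_that("interaction z-score is calibrated on random labels", {
  set.seed(68)
  pts <- random_points(400, lim = 600)
  extreme <- 0L
  for (i in 1:20) {
    lab <- sample(c("A", "B", "bg"), 400, replace = TRUE,
                  prob = c(0.2, 0.2, 0.6))
    z <- interaction_zscore(pts, lab == "A", lab == "B", n_perm = 100,
                            seed = i)$z
    if (abs(z) >= 3) extreme <- extreme + 1L
  }
  expect_lte(extreme, 1L)
})

test_that("constructed enrichment yields a large positive z", {
  set.seed(69)
  A <- random_points(10, lim = 1000)
  # place every B within 50 um of an A cell
  B <- A[sample(10, 60, replace = TRUE), ] +
    matrix(runif(120, -35, 35), 60, 2)
  bg <- random_points(200, lim = 1000)
  pts <- rbind(A, B, bg)
  is_a <- c(rep(TRUE, 10), rep(FALSE, 260))
  is_b <- c(rep(FALSE, 10), rep(TRUE, 60), rep(FALSE, 200))
  z <- interaction_zscore(pts, is_a, is_b, n_perm = 200, seed = 1)$z
  expect_gt(z, 5)
  expect_error(interaction_zscore(pts, is_a, is_b, n_perm = 0), "n_perm")
  expect_true(is.na(interaction_zscore(pts, rep(FALSE, 420), is_b,
                                       n_perm = 10)$z))
})
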