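planted_matrix <- function(n = 80, p = 120, s = 5, beta = 2, seed = 1) {
  with_seed <- function(seed, expr) { set.seed(seed); expr }
  with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("f", seq_len(p))
    b <- c(rep(beta, s), rep(0, p - s))
    eta <- as.numeric(X %*% b)
    list(X = X, eta = eta,
         time = rexp(n, exp(eta)), event = rep(1, n),
         informative = paste0("f", seq_len(s)))
  })
}

test_that("permutation decoys preserve marginals and double the matrix", {
  set.seed(81)
  X <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("v", 1:8)))
  Xa <- inject_decoys(X, "permutation", seed = 3)
  expect_equal(ncol(Xa), 16)
  expect_equal(sum(attr(Xa, "is_decoy")), 8)
  for (j in 1:8)
    expect_equal(sort(Xa[, 8 + j]), sort(X[, j]))  # identical histogram
  # deterministic under seed
  expect_identical(Xa, inject_decoys(X, "permutation", seed = 3))
})

test_that("decoy-outcome correlations follow the exchangeable null", {
  set.seed(82)
  n <- 100
  cors <- replicate(30, {
    X <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(NULL, paste0("v", 1:20)))
    y <- X[, 1] + rnorm(n)           # outcome tied to a real feature
    Xa <- inject_decoys(X, "permutation", seed = sample.int(1e6, 1))
    as.numeric(cor(Xa[, 21:40], y))
  })
  # null correlations: mean ~0, sd ~1/sqrt(n), no heavy excess
  expect_lt(abs(mean(cors)), 0.02)
  expect_lt(abs(sd(cors) - 1 / sqrt(n)), 0.02)
  expect_lt(max(abs(cors)), 5 / sqrt(n))
})

test_that("knockoffs match second moments and flag singular covariance", {
  set.seed(83)
  n <- 300; p <- 6
  S <- 0.5 ^ abs(outer(1:p, 1:p, "-"))
  X <- matrix(rnorm(n * p), n, p) %*% chol(S)
  colnames(X) <- paste0("v", 1:p)
  Xa <- inject_decoys(X, "knockoff", seed = 5)
  K <- Xa[, (p + 1):(2 * p)]
  expect_lt(max(abs(colMeans(K) - colMeans(X))), 0.15)
  expect_lt(max(abs(cov(K) - cov(X))), 0.25)
  # cross-covariance between X_j and knockoff_k (j != k) matches Sigma too
  cc <- cov(X, K)
  expect_lt(max(abs(cc[upper.tri(cc)] - S[upper.tri(S)])), 0.25)
  # p > n covariance must be regularized, with a warning
  Xs <- matrix(rnorm(10 * 30), 10, 30,
               dimnames = list(NULL, paste0("w", 1:30)))
  expect_warning(inject_decoys(Xs, "knockoff", seed = 1), "singular")
})

test_that("planted features are selected and decoys never returned", {
  pm <- planted_matrix(n = 100, p = 150, s = 5, beta = 2, seed = 84)
  cfg <- selection_config(n_subsamples = 50, endpoint = "cox", seed = 7)
  sel <- select_features(pm$X, data.frame(time = pm$time,
                                          event = pm$event), cfg)
  expect_gte(sum(pm$informative %in% sel$selected), 4)
  expect_false(any(startsWith(sel$selected, "decoy__")))
  expect_true(all(sel$freq_real >= 0 & sel$freq_real <= 1))
  expect_lte(sel$estimated_fdp, cfg$fdp_cap)
  # reproducible under the same seed
  sel2 <- select_features(pm$X, data.frame(time = pm$time,
                                           event = pm$event), cfg)
  expect_identical(sel$freq_real, sel2$freq_real)
  expect_identical(sel$selected, sel2$selected)
})

test_that("pure-noise designs select nothing almost always", {
  set.seed(85)
  empty <- 0L
  for (r in 1:10) {
    n <- 60; p <- 150
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", 1:p)))
    y <- rbinom(n, 1, 0.5)
    cfg <- selection_config(n_subsamples = 50, seed = 1000 + r)
    sel <- select_features(X, y, cfg)
    if (length(sel$selected) == 0) empty <- empty + 1L
  }
  expect_gte(empty, 9L)
})

test_that("estimated FDP curve follows its defining formula", {
  pm <- planted_matrix(n = 80, p = 100, s = 4, beta = 2, seed = 86)
  cfg <- selection_config(n_subsamples = 50, endpoint = "cox", seed = 3)
  sel <- select_features(pm$X, data.frame(time = pm$time,
                                          event = pm$event), cfg)
  cv <- sel$fdp_curve
  recompute <- vapply(cv$threshold, function(t)
    (1 + sum(sel$freq_decoy >= t)) /
      max(1, sum(sel$freq_real >= t)), numeric(1))
  expect_equal(cv$fdp, recompute, tolerance = 1e-12)
})

test_that("duplicating a selected feature barely moves other frequencies", {
  pm <- planted_matrix(n = 100, p = 60, s = 3, beta = 2, seed = 87)
  cfg <- selection_config(n_subsamples = 100, endpoint = "cox", seed = 5)
  y <- data.frame(time = pm$time, event = pm$event)
  sel1 <- select_features(pm$X, y, cfg)
  X2 <- cbind(pm$X, dup = pm$X[, "f1"] + rnorm(100, sd = 1e-8))
  sel2 <- select_features(X2, y, cfg)
  common <- setdiff(colnames(pm$X), "f1")
  expect_lt(max(abs(sel1$freq_real[common] - sel2$freq_real[common])),
            0.15)
})

test_that("grouped subsampling draws half of each cohort", {
  pm <- planted_matrix(n = 80, p = 40, s = 2, beta = 2, seed = 88)
  cohort <- rep(c("A", "B"), each = 40)
  cfg <- selection_config(n_subsamples = 50, endpoint = "cox",
                          grouped = TRUE, seed = 9)
  sel <- select_features(pm$X, data.frame(time = pm$time,
                                          event = pm$event), cfg,
                         cohort = cohort)
  expect_s3_class(sel, "stabl_selection")
  expect_equal(sel$n_fit, 50L)
  # config validation
  expect_error(selection_config(fraction = 1.2), "fraction")
  expect_error(selection_config(n_subsamples = 10), "50")
  expect_error(select_features(pm$X, data.frame(time = pm$time,
                                                event = rep(0, 80)),
                               cfg), "censored")
})

test_that("per-family selection unions family-level calls", {
  co <- small_cohort()
  set.seed(89)
  n <- 40
  clin <- data.frame(patient_id = sprintf("p%02d", 1:n))
  recs <- do.call(rbind, lapply(1:30, function(j) {
    fam <- if (j <= 15) "gcross|cn2|tumor|a|b" else "jsd|cn2|tumor|a|b"
    data.frame(patient_id = clin$patient_id,
               feature = sub("a\\|b", paste0("a", j, "|b"), fam),
               value = runif(n))
  }))
  fm <- assemble_features(recs, clin, min_unique = 10)
  y <- rbinom(n, 1, 0.5)
  out <- select_features_by_family(
    fm, y, selection_config(n_subsamples = 50, seed = 4))
  expect_named(out, c("selected", "by_family"))
  expect_setequal(names(out$by_family),
                  c("gcross.cn2", "jsd.cn2"))
  expect_true(all(out$selected %in% colnames(fm$scaled)))
})
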