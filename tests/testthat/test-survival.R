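test_that("Mann-Whitney enrichment matches exact enumeration", {
  X <- cbind(f1 = c(1, 2, 3, 4, 5, 6))
  g <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  out <- mwu_enrichment(X, g)
  # the most extreme of the 20 arrangements of 3+3 ranks, two-sided
  expect_equal(out$p, 2 * 1 / 20)
  # identical groups give p = 1
  X2 <- cbind(f1 = rep(c(1, 2, 3), 2))
  expect_equal(mwu_enrichment(X2, g)$p, 1)
  # constant feature: p = 1 by convention
  expect_equal(mwu_enrichment(cbind(f1 = rep(2, 6)), g)$p, 1)
})

test_that("BH adjustment is monotone and never below the raw p", {
  set.seed(91)
  X <- matrix(rexp(40 * 20), 40, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  X[, 1] <- X[, 1] + rep(c(0, 2), each = 20)
  g <- rep(c(FALSE, TRUE), each = 20)
  out <- mwu_enrichment(X, g)
  expect_true(all(out$p_adj >= out$p - 1e-12))
  ord <- order(out$p)
  expect_true(all(diff(out$p_adj[ord]) >= -1e-12))
  expect_equal(out$p_adj, p.adjust(out$p, "BH"))
  # fold change direction: group TRUE has higher median on f1
  expect_gt(out$log2fc[out$feature == "f1"], 0)
})

test_that("univariate Cox recovers a known hazard ratio", {
  set.seed(92)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.1 * 2^x)          # true HR = 2
  out <- univariate_cox(cbind(grp = x), tt, rep(1, n))
  expect_lt(abs(out$loghr - log(2)), 0.2)
  expect_true(out$converged)
  # all-zero feature flagged non-informative
  out0 <- univariate_cox(cbind(z = rep(0, n)), tt, rep(1, n))
  expect_false(out0$converged)
  expect_true(is.na(out0$p_adj))
})

test_that("null covariates give uniform Cox p-values", {
  set.seed(93)
  ps <- replicate(200, {
    n <- 60
    x <- rnorm(n)
    tt <- rexp(n, 0.1)
    univariate_cox(cbind(x = x), tt, rep(1, n))$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Cox confidence intervals achieve nominal coverage", {
  set.seed(94)
  hits <- 0L
  B <- 500
  for (i in seq_len(B)) {
    n <- 120
    x <- rnorm(n)
    tt <- rexp(n, 0.1 * exp(0.5 * x))
    out <- univariate_cox(cbind(x = x), tt, rep(1, n))
    lo <- out$loghr - 1.96 * out$se
    hi <- out$loghr + 1.96 * out$se
    if (lo <= 0.5 && 0.5 <= hi) hits <- hits + 1L
  }
  expect_gte(hits / B, 0.93)
  expect_lte(hits / B, 0.97)
})

test_that("log-rank median split behaves at the degenerate corners", {
  # identical survival in both strata: chi-square 0, p = 1
  tt <- rep(c(2, 4, 6, 8), 2)
  ev <- rep(1, 8)
  g <- rep(c("a", "b"), each = 4)
  km <- km_logrank(NULL, tt, ev, groups = g)
  expect_lt(km$chisq, 1e-9)
  expect_equal(km$p, 1)
  # strata swap leaves the statistic unchanged
  set.seed(95)
  sc <- rnorm(40); tt2 <- rexp(40, 0.1 * exp(sc)); ev2 <- rep(1, 40)
  k1 <- km_logrank(sc, tt2, ev2)
  k2 <- km_logrank(-sc, tt2, ev2)
  expect_equal(k1$chisq, k2$chisq, tolerance = 1e-9)
  expect_error(km_logrank(NULL, tt, ev, groups = rep("a", 8)),
               "degenerate")
})

test_that("planted hazard ratio 3 is detected with high power", {
  set.seed(96)
  hits <- 0L
  for (i in 1:20) {
    n <- 200
    g <- rep(0:1, each = n / 2)
    tt <- rexp(n, 0.08 * 3^g)
    km <- km_logrank(g + rnorm(n, sd = 1e-9), tt, rep(1, n))
    if (km$p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("IPCW time-dependent AUC hits the analytic corners", {
  # perfectly separating score, no censoring before the horizon
  tt <- c(1, 2, 3, 10, 11, 12)
  ev <- rep(1, 6)
  score <- c(6, 5, 4, 3, 2, 1)      # higher score = earlier event
  auc <- td_auc_ipcw(score, tt, ev, times = c(5, 8))
  expect_equal(auc$auc, c(1, 1))
  # random score concentrates near 0.5
  set.seed(97)
  n <- 400
  tt2 <- rexp(n, 0.1); sc2 <- rnorm(n)
  a <- td_auc_ipcw(sc2, tt2, rep(1, n), times = 3:24)
  expect_true(all(a$auc > 0.35 & a$auc < 0.65, na.rm = TRUE))
  # no cases yet -> NA
  expect_true(is.na(td_auc_ipcw(score, tt, ev, times = 0.5)$auc))
})

test_that("oracle risk scores give high cross-validated AUC, random low", {
  set.seed(98)
  n <- 200; p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  eta <- as.numeric(X %*% c(1.5, 1.2, 1, 0, 0))
  tt <- rexp(n, 0.05 * exp(eta)); ev <- rep(1, n)
  cv <- kfold_cox_auc(X, tt, ev, k = 10, seed = 3)
  ok <- cv$auc$time >= 3
  expect_gte(mean(cv$auc$mean[ok], na.rm = TRUE), 0.9)
  expect_true(all(cv$features$ci_lo <= cv$features$loghr &
                    cv$features$loghr <= cv$features$ci_hi, na.rm = TRUE))
  # pure-noise features give a band around 0.5
  Xn <- matrix(rnorm(n * p), n, p,
               dimnames = list(NULL, paste0("g", 1:p)))
  ttn <- rexp(n, 0.05)
  cvn <- kfold_cox_auc(Xn, ttn, ev, k = 10, seed = 4)
  expect_true(mean(cvn$auc$mean, na.rm = TRUE) > 0.4 &&
                mean(cvn$auc$mean, na.rm = TRUE) < 0.6)
})

test_that("prognosis scores are linear in the weights and prognostic", {
  # score = sum w_k z_k exactly
  tab <- data.frame(feature = c("a", "b"), loghr = c(0.5, 0.5))
  X <- cbind(a = c(1, 2), b = c(-1, 0))
  pg <- prognosis_score(tab, X)
  expect_equal(pg$score, c(0, 1))
  # flipping weights negates scores
  tab2 <- tab; tab2$loghr <- -tab2$loghr
  expect_equal(prognosis_score(tab2, X)$score, -pg$score)
  # subset partition: resistance and response are disjoint and exhaustive
  tab3 <- data.frame(feature = c("a", "b", "c"),
                     loghr = c(0.8, -0.4, 0.2))
  X3 <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  res <- prognosis_score(tab3, X3, subset = "resistance")
  rsp <- prognosis_score(tab3, X3, subset = "response")
  expect_setequal(c(names(res$weights), names(rsp$weights)),
                  tab3$feature)
  expect_length(intersect(names(res$weights), names(rsp$weights)), 0)
  # on planted data the high-score group progresses earlier
  set.seed(99)
  hits <- 0L
  for (i in 1:10) {
    n <- 120
    Xp <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
    eta <- Xp %*% c(1, 0.8)
    tt <- rexp(n, 0.08 * exp(eta))
    uv <- univariate_cox(Xp, tt, rep(1, n))
    pgp <- prognosis_score(uv, Xp, tt, rep(1, n))
    med <- median(pgp$score)
    hi <- pgp$score > med
    if (pgp$km$p < 0.05 &&
          median(tt[hi]) < median(tt[!hi])) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
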