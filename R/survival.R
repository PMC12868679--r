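#' Mann-Whitney group enrichment per feature
#'
#' Two-sided Mann-Whitney U tests of each feature between two outcome
#' groups (exact for small samples without ties, normal approximation
#' otherwise, as in [stats::wilcox.test()]), log2 fold change of group
#' medians (with a pseudocount guarding zero medians), and
#' Benjamini-Hochberg adjustment across the tested features. Constant
#' features get p = 1 by convention.
#'
#' @param X feature matrix (patients x features), raw scale.
#' @param groups logical or two-level vector; `TRUE`/second level is the
#'   "case" group for the fold change.
#' @param pseudocount added to both medians in the fold change.
#' @return data.frame (feature, U, p, log2fc, p_adj).
#' @export
mwu_enrichment <- function(X, groups, pseudocount = 1e-6) {
  X <- as.matrix(X)
  g <- as.logical(groups)
  if (!any(g) || !any(!g)) stopf("both groups must be non-empty")
  res <- lapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    if (length(unique(v)) == 1)
      return(c(U = NA_real_, p = 1,
               log2fc = 0))
    wt <- suppressWarnings(wilcox.test(v[g], v[!g]))
    m1 <- median(v[g]); m0 <- median(v[!g])
    # fold change is meaningful for non-negative features (proportions,
    # counts); features straddling zero get NA
    fc <- if (m1 >= 0 && m0 >= 0)
      log2((m1 + pseudocount) / (m0 + pseudocount)) else NA_real_
    c(U = unname(wt$statistic), p = wt$p.value, log2fc = fc)
  })
  out <- data.frame(feature = colnames(X) %||% seq_len(ncol(X)),
                    do.call(rbind, res))
  out$p_adj <- p.adjust(out$p, "BH")
  out
}

#' Univariate Cox regression per feature
#'
#' One proportional-hazards fit per feature on its continuous (scaled)
#' value, with BH false-discovery adjustment across features.
#' Non-converged or degenerate fits are flagged and excluded from the
#' adjustment denominator.
#'
#' @param X feature matrix (patients x features).
#' @param time,event survival time and event indicator.
#' @return data.frame (feature, loghr, se, p, converged, p_adj).
#' @export
univariate_cox <- function(X, time, event) {
  X <- as.matrix(X)
  y <- survival::Surv(time, as.numeric(event))
  res <- lapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    if (var(v) == 0)
      return(data.frame(loghr = NA_real_, se = NA_real_, p = NA_real_,
                        converged = FALSE))
    fit <- tryCatch(
      suppressWarnings(survival::coxph(y ~ v, data = data.frame(v = v))),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(coef(fit)[1]))
      return(data.frame(loghr = NA_real_, se = NA_real_, p = NA_real_,
                        converged = FALSE))
    s <- summary(fit)
    data.frame(loghr = unname(coef(fit)[1]),
               se = s$coefficients[1, "se(coef)"],
               p = s$coefficients[1, "Pr(>|z|)"], converged = TRUE)
  })
  out <- cbind(data.frame(feature = colnames(X) %||% seq_len(ncol(X))),
               do.call(rbind, res))
  out$p_adj <- NA_real_
  out$p_adj[out$converged] <- p.adjust(out$p[out$converged], "BH")
  out
}

#' Kaplan-Meier comparison by median split
#'
#' Splits patients at the median of a score (above vs at-or-below) and
#' compares the strata with a two-sided log-rank test (1 df). Explicit
#' strata can be passed instead of a score.
#'
#' @param score numeric per-patient score (median split), or `NULL` when
#'   `groups` is given.
#' @param time,event survival data.
#' @param groups optional explicit two-level stratification.
#' @return object of class `km_fit`: `chisq`, `p`, `fit`
#'   (a [survival::survfit()] with 95% CI), `groups`.
#' @export
km_logrank <- function(score = NULL, time, event, groups = NULL) {
  if (is.null(groups)) {
    if (is.null(score)) stopf("need a score or explicit groups")
    groups <- factor(ifelse(score > median(score), "high", "low"),
                     levels = c("low", "high"))
  } else groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stopf("degenerate stratification: a stratum is empty")
  y <- survival::Surv(time, as.numeric(event))
  sd_ <- survival::survdiff(y ~ g, data = data.frame(g = groups))
  p <- pchisq(sd_$chisq, df = length(sd_$n) - 1, lower.tail = FALSE)
  fit <- survival::survfit(y ~ g, data = data.frame(g = groups),
                           conf.int = 0.95)
  structure(list(chisq = unname(sd_$chisq), p = p, fit = fit,
                 groups = groups), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square %.3f (1 df), p = %.4g\n",
              x$chisq, x$p))
  invisible(x)
}

#' @export
plot.km_fit <- function(x, ...) {
  graphics::plot(x$fit, col = c(4, 2), conf.int = TRUE,
                 xlab = "time (months)", ylab = "survival", ...)
  graphics::legend("topright", levels(x$groups), col = c(4, 2), lty = 1)
  invisible(x)
}

#' IPCW time-dependent (cumulative/dynamic) AUC
#'
#' Discrimination of a risk score for events occurring by each horizon t:
#' cases are subjects with an observed event by t, controls those still at
#' risk beyond t; case contributions are weighted by the inverse
#' probability of censoring \eqn{1/\hat G(T_i^-)} (Kaplan-Meier of the
#' censoring distribution), and concordant score pairs are counted with
#' ties scoring 1/2. With a perfectly separating score and no censoring
#' the estimate is exactly 1.
#'
#' @param score risk score (higher = higher risk).
#' @param time,event survival data used for evaluation.
#' @param times horizons at which to evaluate.
#' @return data.frame (time, auc); `auc` is NA where no case or no control
#'   exists.
#' @export
td_auc_ipcw <- function(score, time, event, times) {
  event <- as.numeric(event)
  n <- length(time)
  # Kaplan-Meier of the censoring distribution G(t)
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  Gfun <- stats::stepfun(cfit$time, c(1, cfit$surv), right = FALSE)
  Gm <- function(t) {
    # left limit G(t-)
    g <- Gfun(t - 1e-9)
    pmax(g, 1e-6)
  }
  vapply(times, function(t) {
    case <- which(time <= t & event == 1)
    ctrl <- which(time > t)
    if (!length(case) || !length(ctrl)) return(NA_real_)
    w <- 1 / Gm(time[case])
    num <- 0
    for (i in seq_along(case)) {
      cmp <- sign(score[case[i]] - score[ctrl])
      num <- num + w[i] * sum((cmp + 1) / 2)
    }
    num / (sum(w) * length(ctrl))
  }, numeric(1)) -> auc
  data.frame(time = times, auc = auc)
}

#' Repeated-split penalized Cox with time-dependent AUC
#'
#' Fits an l1-regularized proportional-hazards model on `k` random
#' train/test splits (default 10 splits at 75%/25%), choosing the penalty
#' by cross-validation within each training set, and evaluates the test-set
#' risk scores by IPCW time-dependent AUC on a monthly grid to
#' `horizon` months. Splits whose test set has no events are redrawn. The
#' returned band is the 5%-95% range of the per-split AUC curves.
#'
#' Per-feature log hazard ratios and 95% CIs are from univariate Cox fits
#' on the full data (a joint unpenalized fit is not estimable when the
#' selected set approaches the cohort size).
#'
#' @param X matrix restricted to the selected features (scaled).
#' @param time,event survival outcome.
#' @param k number of random splits.
#' @param split training fraction.
#' @param horizon last month of the AUC grid.
#' @param seed RNG seed.
#' @return object of class `cox_cv`: `auc` (data.frame time, mean, lo,
#'   hi), `auc_splits`, `features` (loghr table), `k`.
#' @export
kfold_cox_auc <- function(X, time, event, k = 10L, split = 0.75,
                          horizon = 24, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  times <- seq(1, horizon)
  event <- as.numeric(event)
  aucs <- matrix(NA_real_, k, length(times))
  with_seed(seed, {
    for (b in seq_len(k)) {
      for (try in seq_len(20L)) {
        tr <- sample.int(n, round(split * n))
        te <- setdiff(seq_len(n), tr)
        if (sum(event[te]) >= 1 && sum(event[tr]) >= 3) break
      }
      risk <- tryCatch({
        if (ncol(X) >= 2) {
          cv <- suppressWarnings(
            glmnet::cv.glmnet(X[tr, ], survival::Surv(time[tr],
                                                      event[tr]),
                              family = "cox", nfolds = 5,
                              standardize = FALSE))
          as.numeric(predict(cv, X[te, , drop = FALSE],
                             s = "lambda.min"))
        } else {
          fit <- survival::coxph(survival::Surv(time[tr], event[tr]) ~ .,
                                 data = data.frame(X[tr, , drop = FALSE]))
          as.numeric(as.matrix(X[te, , drop = FALSE]) %*% coef(fit))
        }
      }, error = function(e) NULL)
      if (is.null(risk)) next
      aucs[b, ] <- td_auc_ipcw(risk, time[te], event[te], times)$auc
    }
  })
  uv <- univariate_cox(X, time, event)
  uv$ci_lo <- uv$loghr - 1.96 * uv$se
  uv$ci_hi <- uv$loghr + 1.96 * uv$se
  auc <- data.frame(
    time = times,
    mean = apply(aucs, 2, mean, na.rm = TRUE),
    lo = apply(aucs, 2, quantile, 0.05, na.rm = TRUE),
    hi = apply(aucs, 2, quantile, 0.95, na.rm = TRUE))
  structure(list(auc = auc, auc_splits = aucs, features = uv, k = k),
            class = "cox_cv")
}

#' @export
print.cox_cv <- function(x, ...) {
  ok <- is.finite(x$auc$mean)
  cat(sprintf("Penalized Cox, %d random splits\n", x$k))
  cat(sprintf("  mean time-dependent AUC over months %d-%d: %.3f\n",
              min(x$auc$time[ok]), max(x$auc$time[ok]),
              mean(x$auc$mean[ok])))
  invisible(x)
}

#' @export
plot.cox_cv <- function(x, ...) {
  ok <- is.finite(x$auc$mean)
  graphics::plot(x$auc$time[ok], x$auc$mean[ok], type = "l", ylim = c(0, 1),
                 xlab = "months", ylab = "time-dependent AUC", ...)
  graphics::lines(x$auc$time[ok], x$auc$lo[ok], lty = 3)
  graphics::lines(x$auc$time[ok], x$auc$hi[ok], lty = 3)
  graphics::abline(h = 0.5, col = "grey")
  invisible(x)
}

#' Prognosis score from per-feature hazard weights
#'
#' Per-patient score \eqn{\sum_k w_k z_{ik}} over the selected features,
#' with weights the per-feature log hazard ratios (`weight = "loghr"`,
#' default) or hazard ratios (`weight = "hr"`). Restriction to the
#' positive-weight subset gives a resistance signature, to the
#' negative-weight subset a response signature. Returns the scores and the
#' median-split Kaplan-Meier comparison.
#'
#' @param fit a `cox_cv` (for its per-feature loghr table) or a data.frame
#'   with `feature` and `loghr`.
#' @param X scaled matrix containing the fit's features.
#' @param time,event survival data for the KM comparison.
#' @param subset `"all"`, `"resistance"` (loghr > 0) or `"response"`
#'   (loghr < 0).
#' @param weight `"loghr"` or `"hr"`.
#' @return list with `score`, `km` ([km_logrank()] result), `weights`.
#' @export
prognosis_score <- function(fit, X, time = NULL, event = NULL,
                            subset = c("all", "resistance", "response"),
                            weight = c("loghr", "hr")) {
  subset <- match.arg(subset); weight <- match.arg(weight)
  tab <- if (inherits(fit, "cox_cv")) fit$features else fit
  tab <- tab[is.finite(tab$loghr), , drop = FALSE]
  if (subset == "resistance") tab <- tab[tab$loghr > 0, , drop = FALSE]
  if (subset == "response") tab <- tab[tab$loghr < 0, , drop = FALSE]
  if (!nrow(tab)) stopf("no features in the requested subset")
  w <- if (weight == "loghr") tab$loghr else exp(tab$loghr)
  names(w) <- tab$feature
  X <- as.matrix(X)[, tab$feature, drop = FALSE]
  score <- as.numeric(X %*% w)
  km <- if (!is.null(time))
    km_logrank(score, time, event) else NULL
  list(score = score, km = km, weights = w)
}
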