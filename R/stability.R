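#' Stability-selection configuration
#'
#' @param n_subsamples number of subsample refits (B, >= 50).
#' @param fraction subsample fraction of patients in (0, 1).
#' @param decoy_mode `"permutation"` (row-permuted copies of each feature)
#'   or `"knockoff"` (second-order Gaussian knockoffs).
#' @param n_lambda,lambda_min_ratio l1 penalty grid: `n_lambda` log-spaced
#'   values from the null-model penalty down to
#'   `lambda_min_ratio * lambda_max`.
#' @param fdp_cap maximum admissible estimated false-discovery proportion;
#'   when no frequency threshold achieves it, nothing is selected.
#' @param min_threshold reliability floor: the frequency threshold may not
#'   fall below this value, so a feature must be selected in at least this
#'   fraction of subsamples regardless of the decoy calibration.
#' @param endpoint `"binary"` (Lasso logistic on a binary outcome, e.g.
#'   clinical benefit) or `"cox"` (l1-penalized Cox on a censored
#'   time-to-event outcome).
#' @param grouped draw the subsample fraction from each cohort separately.
#' @param min_events minimum events per Cox subsample (redraw up to 10x).
#' @param seed RNG seed.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(n_subsamples = 100L, fraction = 0.5,
                             decoy_mode = c("permutation", "knockoff"),
                             n_lambda = 30L, lambda_min_ratio = 0.1,
                             fdp_cap = 0.5, min_threshold = 0.6,
                             endpoint = c("binary", "cox"),
                             grouped = FALSE, min_events = 10L,
                             seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0,1)")
  if (n_subsamples < 50) stopf("need at least 50 subsamples")
  structure(list(n_subsamples = as.integer(n_subsamples),
                 fraction = fraction,
                 decoy_mode = match.arg(decoy_mode),
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 fdp_cap = fdp_cap, min_threshold = min_threshold,
                 endpoint = match.arg(endpoint),
                 grouped = grouped, min_events = as.integer(min_events),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Inject decoy features
#'
#' Pairs every real feature with an artificial one that carries the same
#' marginal distribution but no association with the outcome. Permutation
#' decoys are independently row-permuted copies of each column; knockoff
#' decoys are second-order Gaussian knockoffs (equi-correlated
#' construction matching the empirical mean and covariance; the covariance
#' is ridge-regularized with a warning when singular, as it must be for
#' p > n).
#'
#' @param X scaled numeric matrix (patients x features).
#' @param mode `"permutation"` or `"knockoff"`.
#' @param seed RNG seed.
#' @return matrix with `2 * ncol(X)` columns; attribute `is_decoy` flags
#'   the decoy columns, whose names get a `decoy__` prefix.
#' @export
inject_decoys <- function(X, mode = c("permutation", "knockoff"),
                          seed = 1L) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  D <- with_seed(seed, {
    if (mode == "permutation") {
      apply(X, 2, sample)
    } else {
      S <- stats::cov(X)
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-8) {
        warnf("singular covariance (p = %d, n = %d); ridge-regularized for knockoffs", p, n)
        S <- S + diag(max(1e-4, -min(ev) + 1e-4), p)
        ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      }
      s <- rep(min(1, 2 * min(ev)), p)
      Sinv_s <- solve(S, diag(s, p))
      mu_ko <- X - X %*% Sinv_s
      C <- 2 * diag(s, p) - diag(s, p) %*% Sinv_s
      C <- (C + t(C)) / 2
      ch <- tryCatch(chol(C), error = function(e)
        chol(C + diag(1e-6, p)))
      mu_ko + matrix(rnorm(n * p), n, p) %*% ch
    }
  })
  colnames(D) <- paste0("decoy__", colnames(X))
  out <- cbind(X, D)
  attr(out, "is_decoy") <- c(rep(FALSE, p), rep(TRUE, p))
  out
}

subsample_rows <- function(n, fraction, cohort, grouped) {
  if (grouped && !is.null(cohort)) {
    unlist(lapply(split(seq_len(n), cohort), function(ix)
      sample(ix, max(1, round(fraction * length(ix))))))
  } else sample.int(n, max(2, round(fraction * n)))
}

#' Decoy-calibrated stability selection
#'
#' Repeatedly refits an l1-penalized model (logistic Lasso for a binary
#' endpoint, penalized Cox for time-to-event) on random half-cohort
#' subsamples of the decoy-augmented matrix. A feature's selection
#' frequency is the fraction of subsamples in which it had a nonzero
#' coefficient at any penalty on the grid. The decoy frequencies calibrate
#' a frequency threshold: the estimated false-discovery proportion at
#' threshold t is `(1 + #decoys >= t) / max(1, #reals >= t)` (the +1 makes
#' the estimate conservative), and the chosen threshold minimizes this
#' over thresholds retaining at least one real feature, subject to the
#' configured cap — if no threshold meets the cap, nothing is selected.
#' Decoys are never returned.
#'
#' @param X scaled feature matrix (patients x features, no missing values),
#'   or a [assemble_features()] result (its `scaled` slot is used).
#' @param outcome logical/0-1 vector (binary endpoint) or a
#'   `survival::Surv` object / `data.frame(time, event)` (cox endpoint).
#' @param config [selection_config()].
#' @param cohort optional cohort id per patient for grouped subsampling.
#' @return object of class `stabl_selection`.
#' @export
select_features <- function(X, outcome, config = selection_config(),
                            cohort = NULL) {
  if (inherits(X, "feature_matrix")) X <- X$scaled
  X <- as.matrix(X)
  if (anyNA(X)) stopf("feature matrix contains missing values")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(X)
  seeds <- derive_seeds(config$seed, 2)
  Xa <- inject_decoys(X, config$decoy_mode, seeds[1])
  is_decoy <- attr(Xa, "is_decoy")

  if (config$endpoint == "cox") {
    if (inherits(outcome, "Surv")) {
      y_time <- outcome[, 1]; y_event <- outcome[, 2]
    } else {
      y_time <- outcome$time %||% outcome$pfs_time
      y_event <- as.numeric(outcome$event %||% outcome$pfs_event)
    }
    if (sum(y_event) == 0) stopf("all observations censored")
  } else {
    yb <- as.numeric(outcome)
    if (!all(yb %in% c(0, 1))) stopf("binary endpoint must be 0/1")
  }

  hits <- numeric(ncol(Xa))
  n_fit <- 0L; n_warn <- 0L
  with_seed(seeds[2], {
    for (b in seq_len(config$n_subsamples)) {
      idx <- NULL
      for (try in seq_len(10L)) {
        cand <- subsample_rows(n, config$fraction, cohort, config$grouped)
        ok <- if (config$endpoint == "cox")
          sum(y_event[cand]) >= config$min_events
        else length(unique(yb[cand])) == 2
        if (ok) { idx <- cand; break }
      }
      if (is.null(idx)) { n_warn <- n_warn + 1L; next }
      warned <- FALSE
      fit <- tryCatch(withCallingHandlers({
        if (config$endpoint == "cox")
          glmnet::glmnet(Xa[idx, ], survival::Surv(y_time[idx],
                                                   y_event[idx]),
                         family = "cox", nlambda = config$n_lambda,
                         lambda.min.ratio = config$lambda_min_ratio,
                         standardize = FALSE)
        else
          glmnet::glmnet(Xa[idx, ], yb[idx], family = "binomial",
                         nlambda = config$n_lambda,
                         lambda.min.ratio = config$lambda_min_ratio,
                         standardize = FALSE)
      }, warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }), error = function(e) NULL)
      if (warned) n_warn <- n_warn + 1L
      if (is.null(fit)) { n_warn <- n_warn + 1L; next }
      beta <- fit$beta
      hits <- hits + as.numeric(Matrix::rowSums(beta != 0) > 0)
      n_fit <- n_fit + 1L
    }
  })
  if (n_fit == 0) stopf("no subsample fit converged")
  freq <- hits / n_fit
  freq_real <- freq[!is_decoy]; names(freq_real) <- colnames(X)
  freq_decoy <- freq[is_decoy]

  thr_grid <- sort(unique(c(freq_real, freq_decoy, 0.01)))
  fdp <- vapply(thr_grid, function(t) {
    nr <- sum(freq_real >= t)
    (1 + sum(freq_decoy >= t)) / max(1, nr)
  }, numeric(1))
  n_real_at <- vapply(thr_grid, function(t) sum(freq_real >= t), numeric(1))
  cand <- which(n_real_at > 0 & thr_grid >= config$min_threshold)
  if (length(cand)) {
    best_fdp <- min(fdp[cand])
    best <- cand[fdp[cand] == best_fdp]
    threshold <- max(thr_grid[best])
  } else {
    best_fdp <- Inf; threshold <- Inf
  }
  if (best_fdp > config$fdp_cap) {
    threshold <- Inf
    selected <- character()
    est_fdp <- best_fdp
  } else {
    selected <- names(freq_real)[freq_real >= threshold]
    est_fdp <- best_fdp
  }
  structure(list(
    freq_real = freq_real, freq_decoy = freq_decoy,
    threshold = threshold, estimated_fdp = est_fdp,
    fdp_curve = data.frame(threshold = thr_grid, fdp = fdp,
                           n_real = n_real_at),
    selected = selected, n_fit = n_fit, n_warn = n_warn,
    config = config), class = "stabl_selection")
}

#' @export
print.stabl_selection <- function(x, ...) {
  cat(sprintf("Decoy-calibrated stability selection (%s endpoint, %s decoys)\n",
              x$config$endpoint, x$config$decoy_mode))
  cat(sprintf("  %d features, %d subsample fits (%d failed)\n",
              length(x$freq_real), x$n_fit, x$n_warn))
  if (is.finite(x$threshold))
    cat(sprintf("  threshold %.3f, estimated FDP %.3f -> %d selected\n",
                x$threshold, x$estimated_fdp, length(x$selected)))
  else
    cat(sprintf("  no threshold met the FDP cap %.2f -> nothing selected\n",
                x$config$fdp_cap))
  invisible(x)
}

#' @export
summary.stabl_selection <- function(object, ...) {
  df <- data.frame(feature = names(object$freq_real),
                   frequency = as.numeric(object$freq_real),
                   selected = names(object$freq_real) %in% object$selected)
  df[order(-df$frequency), ]
}

#' @export
plot.stabl_selection <- function(x, ...) {
  graphics::plot(x$fdp_curve$threshold, pmin(x$fdp_curve$fdp, 2),
                 type = "s", xlab = "frequency threshold",
                 ylab = "estimated FDP", ...)
  if (is.finite(x$threshold))
    graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}

#' Per-family stability selection
#'
#' Runs [select_features()] within each feature family of an assembled
#' matrix and unions the selected sets — selection is calibrated per
#' family, mirroring how spatial feature families differ in dimensionality
#' and correlation structure.
#'
#' @param fm [assemble_features()] result.
#' @param outcome endpoint (see [select_features()]).
#' @param config [selection_config()].
#' @param cohort optional cohort ids for grouped subsampling.
#' @param min_features families smaller than this are skipped.
#' @return list with `selected` (union), `by_family` (per-family
#'   `stabl_selection` objects).
#' @export
select_features_by_family <- function(fm, outcome,
                                      config = selection_config(),
                                      cohort = NULL, min_features = 2L) {
  stopifnot(inherits(fm, "feature_matrix"))
  fams <- unique(fm$family)
  out <- list()
  seeds <- derive_seeds(config$seed, length(fams))
  for (i in seq_along(fams)) {
    cols <- which(fm$family == fams[i])
    if (length(cols) < min_features) next
    cfg <- config; cfg$seed <- seeds[i]
    out[[fams[i]]] <- select_features(fm$scaled[, cols, drop = FALSE],
                                      outcome, cfg, cohort)
  }
  list(selected = unique(unlist(lapply(out, `[[`, "selected"))),
       by_family = out)
}

#' Write selection results as CSV
#' @param sel `stabl_selection` or result of [select_features_by_family()].
#' @param path CSV path.
#' @export
write_selection <- function(sel, path) {
  if (!is.null(sel$by_family)) {
    df <- do.call(rbind, lapply(names(sel$by_family), function(f) {
      s <- sel$by_family[[f]]
      data.frame(family = f, feature = names(s$freq_real),
                 frequency = as.numeric(s$freq_real),
                 selected = names(s$freq_real) %in% s$selected)
    }))
  } else {
    df <- summary(sel)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
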