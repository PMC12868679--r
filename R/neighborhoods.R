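#' KNN composition histograms
#'
#' For every cell, describe its spatial surroundings by the composition of
#' its `N` nearest neighbours (self excluded) within the same core. Two
#' bases are supported:
#' \describe{
#'   \item{tumor}{binary tumor / non-tumor neighbour frequencies (two
#'     columns, normalized to sum 1) — the basis for cellular
#'     neighbourhoods;}
#'   \item{metabolic}{raw counts of neighbours positive for each of the 7
#'     metabolic pathways. A neighbour positive for several pathways
#'     contributes to each, so row sums may exceed `N`; counts are kept
#'     unnormalized so that overall metabolic density is part of the
#'     signal.}
#' }
#' Cells in cores with fewer than `N + 1` cells get `NA` rows and a
#' warning; artifact cells are excluded throughout.
#'
#' @param cells phenotyped cell table.
#' @param N window size (number of neighbours).
#' @param basis `"tumor"` or `"metabolic"`.
#' @param panel [panel_config()].
#' @return numeric matrix (cells x basis labels) aligned with `cells` rows.
#' @export
knn_composition <- function(cells, N, basis = c("tumor", "metabolic"),
                            panel = default_panel()) {
  basis <- match.arg(basis)
  n <- nrow(cells)
  if (basis == "tumor") {
    out <- matrix(NA_real_, n, 2,
                  dimnames = list(NULL, c("tumor", "nontumor")))
    lab <- cells$cell_type %in% panel$tumor_types
  } else {
    pws <- names(panel$pathway_map)
    out <- matrix(NA_real_, n, length(pws), dimnames = list(NULL, pws))
    ind <- sapply(pws, function(pw) {
      as.numeric(cells[[pos_cols(panel$pathway_map[[pw]])]])
    })
  }
  keep <- cells$cell_type != "artifact"
  for (core in unique(cells$core_id)) {
    idx <- which(cells$core_id == core & keep)
    if (length(idx) < N + 1) {
      warnf("core '%s' has %d cells (< N+1 = %d); left unlabelled",
            core, length(idx), N + 1)
      next
    }
    co <- as.matrix(cells[idx, c("x_um", "y_um")])
    nn <- cpp_knn(co, co, N, TRUE)
    if (basis == "tumor") {
      lv <- lab[idx]
      cnt <- rowSums(matrix(lv[nn], nrow = length(idx)))
      out[idx, ] <- cbind(cnt, N - cnt) / N
    } else {
      acc <- matrix(0, length(idx), ncol(out))
      for (j in seq_len(N)) acc <- acc + ind[idx[nn[, j]], , drop = FALSE]
      out[idx, ] <- acc
    }
  }
  out
}

semantic_labels <- function(centroids, basis) {
  K <- nrow(centroids)
  if (basis == "tumor") {
    ord <- order(centroids[, "tumor"])  # ascending tumor fraction
    lab <- character(K)
    lab[ord[1]] <- "stroma"
    lab[ord[K]] <- "tumor"
    if (K == 3) lab[ord[2]] <- "interface"
    if (K > 3) lab[ord[2:(K - 1)]] <- paste0("interface", seq_len(K - 2))
  } else {
    ord <- order(rowSums(centroids))    # ascending total pathway positivity
    base <- c("minimal", "low", "medium_regulatory", "high")
    lab <- character(K)
    lab[ord] <- if (K == 4) base else paste0("mbn", seq_len(K))
  }
  lab
}

#' Fit a neighbourhood model by k-means
#'
#' Cohort-level k-means (Lloyd, 10 restarts, fixed seed) on the KNN
#' composition histograms, followed by semantic labelling of the clusters:
#' the tumor basis orders clusters by mean tumor fraction (highest =
#' `tumor`, lowest = `stroma`, middle = `interface`); the metabolic basis
#' orders by mean total pathway positivity (`minimal`, `low`,
#' `medium_regulatory`, `high`).
#'
#' @param histograms matrix from [knn_composition()] (NA rows allowed, left
#'   unlabelled).
#' @param K number of clusters.
#' @param seed RNG seed for the restarts.
#' @param basis `"tumor"` or `"metabolic"` (defaults to `"tumor"` for
#'   2-column input).
#' @return `nbhd_model` with per-cell semantic `labels`, `centroids`,
#'   `label_map`, and `inertia`.
#' @export
fit_neighborhoods <- function(histograms, K, seed = 1L,
                              basis = if (ncol(histograms) == 2) "tumor"
                                      else "metabolic") {
  ok <- complete.cases(histograms)
  H <- histograms[ok, , drop = FALSE]
  ndist <- nrow(unique(H))
  if (ndist < K)
    stopf("degenerate clustering: only %d distinct histogram(s) for K = %d",
          ndist, K)
  km <- with_seed(seed, suppressWarnings(
    kmeans(H, centers = K, nstart = 10, iter.max = 100,
           algorithm = "Lloyd")))
  lab_map <- semantic_labels(km$centers, basis)
  labels <- rep(NA_character_, nrow(histograms))
  labels[ok] <- lab_map[km$cluster]
  structure(list(
    basis = basis, K = K, centroids = km$centers, label_map = lab_map,
    labels = labels, inertia = km$tot.withinss, seed = seed
  ), class = "nbhd_model")
}

#' @export
print.nbhd_model <- function(x, ...) {
  cat(sprintf("Neighbourhood model (%s basis, K = %d)\n", x$basis, x$K))
  tb <- table(x$labels, useNA = "ifany")
  for (nm in names(tb)) cat(sprintf("  %-18s %d cells\n", nm, tb[[nm]]))
  cat(sprintf("  inertia %.4g\n", x$inertia))
  invisible(x)
}

#' Assign new histograms to the fitted clusters
#' @param object an `nbhd_model`.
#' @param newdata histogram matrix with the model's columns.
#' @param ... unused.
#' @return character vector of semantic labels (`NA` for incomplete rows).
#' @export
predict.nbhd_model <- function(object, newdata, ...) {
  ok <- complete.cases(newdata)
  out <- rep(NA_character_, nrow(newdata))
  if (any(ok)) {
    X <- newdata[ok, , drop = FALSE]
    d2 <- sapply(seq_len(nrow(object$centroids)), function(k)
      rowSums(sweep(X, 2, object$centroids[k, ])^2))
    d2 <- matrix(d2, nrow = sum(ok))
    out[ok] <- object$label_map[max.col(-d2, ties.method = "first")]
  }
  out
}

#' Inertia curve and elbow (knee) estimate
#'
#' Runs k-means over `K_range` and locates the knee by the maximum
#' distance-to-chord rule on the normalized inertia curve. To keep the
#' curve monotone non-increasing, each K is fitted both with random
#' restarts and with a greedy initialization that extends the previous
#' solution's centroids by the worst-fit point; the better fit wins.
#'
#' The knee score is the maximum perpendicular distance to the chord after
#' scaling both axes to [0,1]; a score below 0.2 indicates no pronounced
#' elbow (`pronounced = FALSE`).
#'
#' @param histograms composition histogram matrix.
#' @param K_range candidate cluster counts within [2, 12].
#' @param seed RNG seed.
#' @return list with `K`, `inertia`, `knee`, `knee_score`, `pronounced`.
#' @export
elbow_inertia <- function(histograms, K_range = 2:8, seed = 1L) {
  if (min(K_range) < 2 || max(K_range) > 12)
    stopf("K_range must lie within [2, 12]")
  K_range <- sort(unique(as.integer(K_range)))
  H <- histograms[complete.cases(histograms), , drop = FALSE]
  inert <- numeric(length(K_range))
  prev <- NULL
  with_seed(seed, {
    for (i in seq_along(K_range)) {
      K <- K_range[i]
      km <- suppressWarnings(
        kmeans(H, centers = K, nstart = 10, iter.max = 100,
               algorithm = "Lloyd"))
      if (!is.null(prev)) {
        # greedy extension of the previous centres guarantees monotonicity
        d2 <- sapply(seq_len(nrow(prev$centers)), function(k)
          rowSums(sweep(H, 2, prev$centers[k, ])^2))
        worst <- which.max(apply(matrix(d2, nrow = nrow(H)), 1, min))
        init <- rbind(prev$centers, H[worst, ])
        init <- init[!duplicated(init), , drop = FALSE]
        if (nrow(init) == K) {
          km2 <- suppressWarnings(
            kmeans(H, centers = init, iter.max = 100, algorithm = "Lloyd"))
          if (km2$tot.withinss < km$tot.withinss) km <- km2
        }
      }
      inert[i] <- km$tot.withinss
      prev <- km
    }
  })
  # distance to chord on the normalized curve
  xs <- (K_range - min(K_range)) / max(1, diff(range(K_range)))
  span <- max(inert) - min(inert)
  ys <- if (span > 0) (inert - min(inert)) / span else rep(0, length(inert))
  # chord from first to last point: distance of (x,y) to line y = 1 - x slope
  x1 <- xs[1]; y1 <- ys[1]; x2 <- xs[length(xs)]; y2 <- ys[length(ys)]
  dd <- abs((y2 - y1) * xs - (x2 - x1) * ys + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  knee <- K_range[which.max(dd)]
  score <- max(dd)
  list(K = K_range, inertia = inert, knee = knee, knee_score = score,
       pronounced = score >= 0.2)
}

#' Annotate a cell table with all three neighbourhood views
#'
#' Fits and applies the tumor/stroma view (window `N = 50`, `K = 2`), the
#' tumor/interface/stroma view (window `N = 30`, `K = 3`), and the
#' metabolic view (window `N = 30`, `K = 4`), cohort-level.
#'
#' @param cells phenotyped cell table (whole cohort).
#' @param panel [panel_config()].
#' @param seed RNG seed (one k-means seed is derived per view).
#' @param windows named list overriding `list(cn2 = 50, cn3 = 30, mbn = 30)`.
#' @return list with annotated `cells` (columns `cn2_label`, `cn3_label`,
#'   `mbn_label`) and the three fitted `models`.
#' @export
annotate_neighborhoods <- function(cells, panel = default_panel(),
                                   seed = 1L,
                                   windows = list(cn2 = 50, cn3 = 30,
                                                  mbn = 30)) {
  seeds <- derive_seeds(seed, 3)
  h2 <- knn_composition(cells, windows$cn2, "tumor", panel)
  m2 <- fit_neighborhoods(h2, 2, seeds[1], "tumor")
  h3 <- knn_composition(cells, windows$cn3, "tumor", panel)
  m3 <- fit_neighborhoods(h3, 3, seeds[2], "tumor")
  hm <- knn_composition(cells, windows$mbn, "metabolic", panel)
  mm <- fit_neighborhoods(hm, 4, seeds[3], "metabolic")
  cells$cn2_label <- m2$labels
  cells$cn3_label <- m3$labels
  cells$mbn_label <- mm$labels
  list(cells = cells, models = list(cn2 = m2, cn3 = m3, mbn = mm))
}

#' Serialize a neighbourhood model (YAML metadata + CSV centroids)
#' @param model `nbhd_model`.
#' @param path base path; writes `<path>.yaml` and `<path>_centroids.csv`.
#' @export
write_nbhd_model <- function(model, path) {
  yaml::write_yaml(list(basis = model$basis, K = model$K,
                        label_map = as.list(model$label_map),
                        inertia = model$inertia, seed = model$seed),
                   paste0(path, ".yaml"))
  write.csv(as.data.frame(model$centroids),
            paste0(path, "_centroids.csv"), row.names = FALSE)
  invisible(path)
}
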