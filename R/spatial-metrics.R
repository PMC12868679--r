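#' G-cross nearest-neighbour distance AUC
#'
#' Empirical cumulative distribution of the distance from each reference
#' cell to its nearest target cell, evaluated on a uniform radius grid up to
#' `r_max` (default 150 µm, chosen below the core radius so boundary bias
#' stays modest; no edge correction is applied). The summary statistic is
#' the exact area under the empirical CDF normalized by `r_max`, so AUC is
#' in [0, 1]: coincident point sets give 1, and a single reference-target
#' pair at distance d gives exactly (r_max - d) / r_max.
#'
#' When reference and target are the same phenotype, pass `self = TRUE`
#' (matched rows) to exclude self-pairs. Empty reference or target sets
#' yield a null result (`auc = NA`), imputed downstream.
#'
#' @param ref,target two-column matrices / data.frames of x,y coordinates
#'   (µm).
#' @param r_max maximum radius (µm).
#' @param n_grid number of grid points (uniform on [0, r_max]).
#' @param self reference and target are the same point set.
#' @return object of class `gcross`: `r` grid, `cdf`, `auc`, `n_ref`,
#'   `n_target`.
#' @export
gcross_auc <- function(ref, target, r_max = 150, n_grid = 151L,
                       self = FALSE) {
  ref <- as.matrix(ref); target <- as.matrix(target)
  r <- seq(0, r_max, length.out = n_grid)
  n_ref <- nrow(ref); n_target <- nrow(target)
  if (n_ref == 0 || n_target == 0 || (self && n_target < 2)) {
    res <- list(r = r, cdf = rep(NA_real_, n_grid), auc = NA_real_,
                n_ref = n_ref, n_target = n_target)
    return(structure(res, class = "gcross"))
  }
  d <- cpp_nn_dist(ref[, 1], ref[, 2], target[, 1], target[, 2], self)
  cdf <- vapply(r, function(ri) mean(d <= ri), numeric(1))
  # exact integral of the empirical CDF up to r_max (the trapezoid rule on
  # the piecewise-constant ECDF), normalized to [0,1]
  auc <- mean(pmax(0, r_max - pmin(d, r_max))) / r_max
  structure(list(r = r, cdf = cdf, auc = auc, n_ref = n_ref,
                 n_target = n_target), class = "gcross")
}

#' @export
print.gcross <- function(x, ...) {
  cat(sprintf("G-cross: %d reference, %d target cells; AUC(<=%g um) = %s\n",
              x$n_ref, x$n_target, max(x$r),
              if (is.na(x$auc)) "NA (empty set)" else sprintf("%.4f", x$auc)))
  invisible(x)
}

#' @export
plot.gcross <- function(x, ...) {
  graphics::plot(x$r, x$cdf, type = "l", xlab = "radius (um)",
                 ylab = "G(r)", ylim = c(0, 1), ...)
  invisible(x)
}

#' Concave-hull (alpha-shape) edge cells per neighbourhood region
#'
#' Flags the cells lying on the alpha-shape boundary of their
#' neighbourhood's point set, per core and per compartment. An edge between
#' two points belongs to the boundary when one of the two radius-`alpha`
#' circles through them is empty of other points. The default alpha is
#' twice the median nearest-neighbour spacing of the region. Degenerate
#' regions (all collinear, or fewer than 4 cells) fall back to the convex
#' hull with a warning.
#'
#' @param cells cell table with neighbourhood labels.
#' @param view label column (`"cn2_label"`, `"cn3_label"`, `"mbn_label"`).
#' @param alpha concavity radius (µm); `NULL` for the per-region default.
#' @return logical vector flagging edge cells, aligned with `cells` rows.
#' @export
edge_cells <- function(cells, view = "cn2_label", alpha = NULL) {
  if (!view %in% names(cells)) stopf("no column '%s' in cell table", view)
  flag <- rep(FALSE, nrow(cells))
  for (core in unique(cells$core_id)) {
    for (comp in stats::na.omit(unique(cells[[view]][cells$core_id == core]))) {
      idx <- which(cells$core_id == core & !is.na(cells[[view]]) &
                     cells[[view]] == comp)
      if (length(idx) < 4) next
      x <- cells$x_um[idx]; y <- cells$y_um[idx]
      if (collinear(x, y)) {
        warnf("core '%s' region '%s' is degenerate; convex hull fallback",
              core, comp)
        flag[idx[grDevices::chull(x, y)]] <- TRUE
        next
      }
      a <- alpha
      if (is.null(a)) {
        nnd <- cpp_nn_dist(x, y, x, y, TRUE)
        a <- 2 * median(nnd)
      }
      on_edge <- cpp_alpha_edges(x, y, a)
      if (!any(on_edge)) {
        # alpha too small to span any pair: fall back to convex hull
        flag[idx[grDevices::chull(x, y)]] <- TRUE
      } else flag[idx] <- on_edge
    }
  }
  flag
}

collinear <- function(x, y) {
  if (length(x) < 3) return(TRUE)
  dx <- x - x[1]; dy <- y - y[1]
  cross <- dx[2] * dy - dy[2] * dx
  all(abs(cross) < 1e-9 * max(1, max(abs(dx)), max(abs(dy))))
}

# Jensen-Shannon distance between two grid PMFs (base 2, square root).
jsd_from_pmf <- function(P, Q) {
  M <- (P + Q) / 2
  kl <- function(p, m) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / m[nz]))
  }
  sqrt(max(0, min(1, 0.5 * kl(P, M) + 0.5 * kl(Q, M))))
}

# All pairwise JSDs among a list of point sets on one shared grid: each
# set's kernel intensity is built once (Scott bandwidth per set, 10 um
# floor, grid padded by 3 max-bandwidths), then pairs are compared.
jsd_matrix <- function(sets, pairs, n_grid = 128L) {
  hs <- lapply(sets, function(P) {
    if (is.null(P) || nrow(P) < 2) return(NULL)
    c(scott_bw(P[, 1]), scott_bw(P[, 2]))
  })
  ok <- !vapply(hs, is.null, logical(1))
  out <- rep(NA_real_, length(pairs))
  if (sum(ok) < 1) return(out)
  allp <- do.call(rbind, sets[ok])
  pad <- 3 * max(unlist(hs[ok]))
  gx <- seq(min(allp[, 1]) - pad, max(allp[, 1]) + pad,
            length.out = n_grid)
  gy <- seq(min(allp[, 2]) - pad, max(allp[, 2]) + pad,
            length.out = n_grid)
  pmfs <- vector("list", length(sets))
  for (i in which(ok))
    pmfs[[i]] <- kde2d_pmf(sets[[i]][, 1], sets[[i]][, 2], hs[[i]],
                           gx, gy)
  for (k in seq_along(pairs)) {
    i <- pairs[[k]][1]; j <- pairs[[k]][2]
    if (ok[i] && ok[j]) out[k] <- jsd_from_pmf(pmfs[[i]], pmfs[[j]])
  }
  out
}

# 2D Gaussian product-kernel density on a rectangular grid, normalized to a
# probability mass function over the grid cells.
kde2d_pmf <- function(x, y, h, gx, gy) {
  Kx <- dnorm(outer(gx, x, "-") / h[1])      # |gx| x n
  Ky <- dnorm(outer(y, gy, "-") / h[2])      # n x |gy|
  z <- Kx %*% Ky
  z / sum(z)
}

scott_bw <- function(v, floor_bw = 10) {
  n <- length(v)
  max(floor_bw, sd(v) * n^(-1 / 6))
}

#' Jensen-Shannon distance between two cell-density estimates
#'
#' Estimates the 2D Gaussian-kernel intensity of each phenotype's point set
#' on a shared grid over the core (bounding box padded by 3 bandwidths),
#' normalizes each to a probability mass function, and returns the
#' Jensen-Shannon *distance* (base-2 logarithm, square root of the
#' divergence), which is a metric bounded in [0, 1]: 0 for complete overlap
#' and 1 for complete separation. Bandwidth is Scott's rule per point set
#' with a 10 µm floor. Either set having fewer than 2 points yields a null
#' result (`distance = NA`); downstream imputation maps nulls to 1.
#'
#' @param a,b two-column coordinate matrices.
#' @param bounds optional `c(xmin, xmax, ymin, ymax)` core bounds; default
#'   is the joint bounding box.
#' @param bandwidth optional fixed bandwidth (µm) for both sets.
#' @param n_grid grid resolution per axis.
#' @return object of class `jsd_result` with `distance`, `bandwidth`,
#'   `n_a`, `n_b`.
#' @export
jsd <- function(a, b, bounds = NULL, bandwidth = NULL, n_grid = 128L) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 2 || nrow(b) < 2) {
    return(structure(list(distance = NA_real_, bandwidth = bandwidth,
                          n_a = nrow(a), n_b = nrow(b)),
                     class = "jsd_result"))
  }
  ha <- if (is.null(bandwidth))
    c(scott_bw(a[, 1]), scott_bw(a[, 2])) else rep(bandwidth, 2)
  hb <- if (is.null(bandwidth))
    c(scott_bw(b[, 1]), scott_bw(b[, 2])) else rep(bandwidth, 2)
  pad <- 3 * max(ha, hb)
  if (is.null(bounds))
    bounds <- c(min(a[, 1], b[, 1]), max(a[, 1], b[, 1]),
                min(a[, 2], b[, 2]), max(a[, 2], b[, 2]))
  gx <- seq(bounds[1] - pad, bounds[2] + pad, length.out = n_grid)
  gy <- seq(bounds[3] - pad, bounds[4] + pad, length.out = n_grid)
  P <- kde2d_pmf(a[, 1], a[, 2], ha, gx, gy)
  Q <- kde2d_pmf(b[, 1], b[, 2], hb, gx, gy)
  structure(list(distance = jsd_from_pmf(P, Q),
                 bandwidth = c(a = ha[1], b = hb[1]),
                 n_a = nrow(a), n_b = nrow(b)), class = "jsd_result")
}

#' @export
print.jsd_result <- function(x, ...) {
  cat(sprintf("Jensen-Shannon distance: %s (n = %d vs %d)\n",
              if (is.na(x$distance)) "NA (insufficient points)"
              else sprintf("%.4f", x$distance), x$n_a, x$n_b))
  invisible(x)
}

#' Permutation interaction z-score
#'
#' Observed mean number of B-phenotype cells within `radius` (default
#' 100 µm) of each A-phenotype cell, compared against a null built by
#' permuting the phenotype labels over the cells of the compartment
#' (positions fixed). Returns `(obs - mean(null)) / sd(null)`.
#'
#' @param coords two-column coordinate matrix for all compartment cells.
#' @param is_a,is_b logical membership vectors for the two phenotypes.
#' @param radius interaction radius (µm).
#' @param n_perm number of label permutations (must be > 0).
#' @param seed RNG seed.
#' @return list with `z`, `observed`, `null_mean`, `null_sd`, `n_perm`;
#'   `z = NA` when either phenotype is absent.
#' @export
interaction_zscore <- function(coords, is_a, is_b, radius = 100,
                               n_perm = 100L, seed = 1L) {
  if (n_perm <= 0) stopf("n_perm must be positive")
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (!any(is_a) || !any(is_b))
    return(list(z = NA_real_, observed = NA_real_, null_mean = NA_real_,
                null_sd = NA_real_, n_perm = n_perm))
  pr <- cpp_radius_pairs(coords[, 1], coords[, 2], radius)
  adj <- Matrix::sparseMatrix(i = pr[, 1], j = pr[, 2], x = 1,
                              dims = c(n, n))
  score <- function(a, b) {
    cnt <- as.numeric(adj %*% as.numeric(b))
    mean(cnt[a])
  }
  obs <- score(is_a, is_b)
  labs <- rep("bg", n); labs[is_a] <- "A"; labs[is_b] <- "B"
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pl <- sample(labs)
    score(pl == "A", pl == "B")
  }, numeric(1)))
  ns <- sd(null)
  list(z = if (ns > 0) (obs - mean(null)) / ns else NA_real_,
       observed = obs, null_mean = mean(null), null_sd = ns,
       n_perm = n_perm)
}
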