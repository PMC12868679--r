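#' Marker positivity threshold from the probability density minimum
#'
#' Cohort-level binary thresholds for each marker are placed at the minimum
#' of a smoothed density estimate of the per-cell positivity probabilities,
#' searched inside a window (default 0.02-0.75). The density is a Gaussian
#' kernel estimate (Scott/`bw.nrd` bandwidth) evaluated on a 512-point grid
#' over [0,1]. A threshold above the cap (default 0.5) is reassigned to the
#' cap; when no interior minimum exists in the window, or fewer than
#' `min_n` values are available, the fallback threshold 0.5 is used.
#'
#' @param probabilities numeric vector in [0,1].
#' @param window search window `c(lo, hi)`.
#' @param cap maximum admissible threshold.
#' @param min_n minimum sample size before falling back.
#' @return scalar threshold in (0, `cap`].
#' @export
threshold_from_density <- function(probabilities, window = c(0.02, 0.75),
                                   cap = 0.5, min_n = 50L) {
  if (length(probabilities) == 0) stopf("empty probability vector")
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE))
    stopf("probabilities must lie in [0,1]")
  probabilities <- probabilities[!is.na(probabilities)]
  if (length(probabilities) < min_n) return(cap)
  d <- tryCatch(
    density(probabilities, bw = "nrd", n = 512, from = 0, to = 1),
    error = function(e) NULL)
  if (is.null(d)) return(cap)
  inside <- d$x >= window[1] & d$x <= window[2]
  xs <- d$x[inside]; ys <- d$y[inside]
  if (length(xs) < 3) return(cap)
  # interior local minima of the smoothed density; a minimum only counts
  # when it is a genuine valley, clearly below both flanking peaks (tail
  # wiggles of a unimodal distribution are not valleys)
  k <- which(diff(sign(diff(ys))) > 0) + 1L
  if (length(k)) {
    valid <- vapply(k, function(i) {
      lp <- max(ys[seq_len(i - 1)])
      rp <- max(ys[seq(i + 1, length(ys))])
      # both flanks must carry a real mode, not tail noise
      min(lp, rp) >= 0.05 * max(ys) && ys[i] < 0.9 * min(lp, rp)
    }, logical(1))
    k <- k[valid]
  }
  if (!length(k)) return(cap)
  thr <- xs[k[which.min(ys[k])]]
  min(thr, cap)
}

#' Fit per-marker thresholds over a cohort
#'
#' @param cells cell table with `<marker>_prob` columns.
#' @param panel [panel_config()].
#' @inheritParams threshold_from_density
#' @return named numeric vector of thresholds (class `threshold_set`).
#' @export
fit_thresholds <- function(cells, panel, window = c(0.02, 0.75), cap = 0.5) {
  markers <- panel_markers(panel)
  thr <- vapply(markers, function(m) {
    col <- prob_cols(m)
    if (!col %in% names(cells)) return(NA_real_)
    threshold_from_density(cells[[col]], window, cap)
  }, numeric(1))
  structure(thr, class = "threshold_set", window = window, cap = cap)
}

#' Apply thresholds to produce binary marker calls
#'
#' `pos = (prob >= threshold)`; equality counts positive.
#'
#' @param cells cell table with probability columns.
#' @param thresholds named per-marker thresholds ([fit_thresholds()]).
#' @param markers markers to call; defaults to all thresholded markers.
#' @return cell table with `<marker>_pos` columns (re)computed.
#' @export
call_markers <- function(cells, thresholds, markers = NULL) {
  if (is.null(markers)) markers <- names(thresholds)[!is.na(thresholds)]
  for (m in markers) {
    if (!m %in% names(thresholds) || is.na(thresholds[[m]]))
      stopf("no threshold for marker '%s'", m)
    col <- prob_cols(m)
    if (!col %in% names(cells))
      stopf("no probability column for marker '%s'", m)
    cells[[pos_cols(m)]] <- cells[[col]] >= thresholds[[m]]
  }
  cells
}

rule_matches <- function(cells, rule, lineage) {
  ok <- rep(TRUE, nrow(cells))
  for (m in rule$pos) ok <- ok & cells[[pos_cols(m)]]
  for (m in rule$neg) ok <- ok & !cells[[pos_cols(m)]]
  ok
}

#' Assign mutually exclusive cell types
#'
#' Cells whose lineage positivity profile exactly matches a phenotype rule
#' receive that rule's type (first match in panel rule order). Cells
#' matching an artifact rule are labelled `"artifact"`. Remaining cells are
#' assigned the modal type among their five nearest exact-match neighbours
#' in marker-probability space (Euclidean over per-marker standardized
#' lineage probabilities); modal-vote ties are broken by the panel's rule
#' order, which makes the assignment independent of row order.
#'
#' @param cells cell table with `<marker>_pos` calls (and `<marker>_prob`
#'   for the fallback).
#' @param panel [panel_config()].
#' @param k_fallback neighbours used for unmatched cells.
#' @return cell table with a `cell_type` column.
#' @export
assign_cell_types <- function(cells, panel, k_fallback = 5L) {
  n <- nrow(cells)
  type <- rep(NA_character_, n)
  for (r in panel$artifact_rules)
    type[is.na(type) & rule_matches(cells, r, panel$lineage_markers)] <-
      "artifact"
  for (r in panel$phenotype_rules)
    type[is.na(type) & rule_matches(cells, r, panel$lineage_markers)] <-
      r$type

  unmatched <- which(is.na(type))
  if (length(unmatched)) {
    pcols <- prob_cols(panel$lineage_markers)
    if (!all(pcols %in% names(cells)))
      stopf("fallback typing needs probability columns for all lineage markers")
    matched <- which(!is.na(type) & type != "artifact")
    rank_of <- setNames(seq_along(panel_cell_types(panel)),
                        panel_cell_types(panel))
    for (core in unique(cells$core_id[unmatched])) {
      um <- unmatched[cells$core_id[unmatched] == core]
      mm <- matched[cells$core_id[matched] == core]
      if (!length(mm))
        stopf("core '%s': no exact-match cells to anchor fallback typing",
              core)
      X <- as.matrix(cells[mm, pcols, drop = FALSE])
      Q <- as.matrix(cells[um, pcols, drop = FALSE])
      mu <- colMeans(X); sdv <- apply(X, 2, sd); sdv[sdv == 0] <- 1
      Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
      Qs <- sweep(sweep(Q, 2, mu), 2, sdv, "/")
      k <- min(k_fallback, nrow(Xs))
      nn <- cpp_knn(Xs, Qs, k, FALSE)
      for (i in seq_along(um)) {
        votes <- table(type[mm[nn[i, ]]])
        best <- names(votes)[votes == max(votes)]
        type[um[i]] <- best[which.min(rank_of[best])]
      }
    }
  }
  cells$cell_type <- type
  cells
}

#' Record functional and metabolic states
#'
#' The functional state set of a cell is its positive functional markers
#' restricted to the admissible set for its lineage (tumor types use the
#' tumor functional set, everything else the immune set). Metabolic states
#' (pathway names whose proxy marker is positive) are recorded for all
#' cell types. States are stored as comma-joined sorted strings in
#' `functional_states` and `metabolic_states`.
#'
#' @param cells cell table with `cell_type` and marker calls.
#' @param panel [panel_config()].
#' @return cell table with state columns.
#' @export
functionalize <- function(cells, panel) {
  n <- nrow(cells)
  is_tumor <- cells$cell_type %in% panel$tumor_types
  fun <- character(n)
  for (m in unique(c(panel$tumor_functional_set,
                     panel$immune_functional_set))) {
    col <- pos_cols(m)
    if (!col %in% names(cells)) next
    allowed <- (is_tumor & m %in% panel$tumor_functional_set) |
      (!is_tumor & m %in% panel$immune_functional_set)
    hit <- allowed & cells[[col]] & cells$cell_type != "artifact"
    fun[hit] <- ifelse(fun[hit] == "", m, paste(fun[hit], m, sep = ","))
  }
  met <- character(n)
  for (pw in sort(names(panel$pathway_map))) {
    col <- pos_cols(panel$pathway_map[[pw]])
    if (!col %in% names(cells)) next
    hit <- cells[[col]] & cells$cell_type != "artifact"
    met[hit] <- ifelse(met[hit] == "", pw, paste(met[hit], pw, sep = ","))
  }
  cells$functional_states <- fun
  cells$metabolic_states <- met
  cells
}

#' Run the full phenotyping stage
#'
#' Thresholds (when probabilities are present and calls are absent or
#' `recall = TRUE`), typing, and state annotation in one call.
#'
#' @param cells cell table.
#' @param panel [panel_config()].
#' @param thresholds optional precomputed [fit_thresholds()] result.
#' @param recall recompute binary calls from probabilities even when
#'   `<marker>_pos` columns already exist.
#' @return list with `cells` (typed, state-annotated) and `thresholds`.
#' @export
phenotype_cells <- function(cells, panel, thresholds = NULL,
                            recall = FALSE) {
  have_pos <- all(pos_cols(panel$lineage_markers) %in% names(cells))
  have_prob <- all(prob_cols(panel$lineage_markers) %in% names(cells))
  if (is.null(thresholds) && have_prob)
    thresholds <- fit_thresholds(cells, panel)
  if ((recall || !have_pos)) {
    if (!have_prob) stopf("probability columns required to call markers")
    cells <- call_markers(cells, thresholds)
  }
  cells <- assign_cell_types(cells, panel)
  cells <- functionalize(cells, panel)
  list(cells = cells, thresholds = thresholds)
}

#' Read / write threshold sets as YAML
#' @param thresholds a `threshold_set`.
#' @param path file path.
#' @rdname threshold_io
#' @export
write_thresholds <- function(thresholds, path) {
  yaml::write_yaml(list(thresholds = as.list(unclass(thresholds)),
                        window = attr(thresholds, "window"),
                        cap = attr(thresholds, "cap")), path,
                   precision = 12)
  invisible(path)
}

#' @rdname threshold_io
#' @export
read_thresholds <- function(path) {
  y <- yaml::read_yaml(path)
  structure(unlist(y$thresholds), class = "threshold_set",
            window = unlist(y$window), cap = y$cap)
}
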