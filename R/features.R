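#' Feature names
#'
#' Engineered features are named by pipe-joined components so that the
#' name parses back to its definition exactly:
#' \preformatted{
#'   prop|<view>|<compartment>|<level>|<phenotype>
#'   ratio|<view>|<compartment>|<a>|<b>
#'   gcross|<view>|<compartment>|<ref>|<target>
#'   gxedge|<view>|<compA>|<compB>|<ref>|<target>
#'   jsd|<view>|<compartment>|<a>|<b>
#'   intz|<view>|<compartment>|<a>|<b>
#' }
#' The feature *family* (the unit of stability selection) is
#' `<kind>.<view>` (plus the level for proportions).
#'
#' @param kind,parts name components (character).
#' @rdname feature_names
#' @export
make_feature_name <- function(kind, ...) {
  parts <- c(kind, ...)
  if (any(grepl("|", parts, fixed = TRUE)))
    stopf("feature name components must not contain '|'")
  paste(parts, collapse = "|")
}

#' @param name a feature name.
#' @return `parse_feature_name`: named list with `kind`, `view`, and the
#'   remaining components.
#' @rdname feature_names
#' @export
parse_feature_name <- function(name) {
  p <- strsplit(name, "|", fixed = TRUE)[[1]]
  out <- switch(p[1],
    prop   = list(kind = p[1], view = p[2], compartment = p[3],
                  level = p[4], phenotype = p[5]),
    ratio  = list(kind = p[1], view = p[2], compartment = p[3],
                  a = p[4], b = p[5]),
    gcross = list(kind = p[1], view = p[2], compartment = p[3],
                  ref = p[4], target = p[5]),
    gxedge = list(kind = p[1], view = p[2], comp_a = p[3], comp_b = p[4],
                  ref = p[5], target = p[6]),
    jsd    = list(kind = p[1], view = p[2], compartment = p[3],
                  a = p[4], b = p[5]),
    intz   = list(kind = p[1], view = p[2], compartment = p[3],
                  a = p[4], b = p[5]),
    stopf("unknown feature kind '%s'", p[1]))
  out
}

feature_family <- function(name) {
  p <- strsplit(name, "|", fixed = TRUE)[[1]]
  if (p[1] == "prop") paste(p[1], p[2], p[4], sep = ".")
  else paste(p[1], p[2], sep = ".")
}

view_column <- function(view) paste0(view, "_label")

rec <- function(patient, feature, value) {
  data.frame(patient_id = patient, feature = feature, value = value,
             stringsAsFactors = FALSE)
}

# phenotype membership matrix builders -------------------------------------

# base: the cell's type; functional: (type, one functional marker);
# metabolic: type x comma-joined pathway state set (a partition).
phenotype_labels <- function(cells, level, panel) {
  if (level == "base") {
    return(cells$cell_type)
  }
  if (level == "metabolic") {
    st <- gsub(",", "+", cells$metabolic_states)
    return(ifelse(st == "", cells$cell_type,
                  paste0(cells$cell_type, ":", st)))
  }
  stopf("phenotype_labels handles base/metabolic levels only")
}

#' Compartment proportions
#'
#' Proportion of each phenotype among all (non-artifact, labelled) cells of
#' each compartment of a neighbourhood view, per patient. Three phenotype
#' levels: `base` cell types (a partition, sums to 1 per compartment);
#' `functional` — cell type crossed with a single positive functional
#' marker (not a partition: a cell with two positive markers contributes to
#' two features); `metabolic` — cell type crossed with its combined
#' metabolic state set (a partition). Phenotypes absent from a compartment
#' score 0; empty compartments yield no records (null, imputed downstream).
#'
#' @param cells annotated cell table.
#' @param view `"cn2"`, `"cn3"` or `"mbn"`.
#' @param level `"base"`, `"functional"` or `"metabolic"`.
#' @param panel [panel_config()].
#' @return long data.frame (patient_id, feature, value).
#' @export
compartment_proportions <- function(cells, view = "cn2", level = "base",
                                    panel = default_panel()) {
  col <- view_column(view)
  if (!col %in% names(cells)) stopf("no column '%s'", col)
  keep <- cells$cell_type != "artifact" & !is.na(cells[[col]])
  cc <- cells[keep, , drop = FALSE]
  out <- list()
  base_types <- panel_cell_types(panel)
  pre <- paste("prop", view, sep = "|")
  for (pid in unique(cc$patient_id)) {
    pc <- cc[cc$patient_id == pid, , drop = FALSE]
    for (comp in unique(pc[[col]])) {
      sub <- pc[pc[[col]] == comp, , drop = FALSE]
      tot <- nrow(sub)
      if (tot == 0) next
      if (level == "functional") {
        feats <- character(); vals <- numeric()
        for (tp in base_types) {
          fs <- if (tp %in% panel$tumor_types) panel$tumor_functional_set
                else panel$immune_functional_set
          sp <- states_split(sub$functional_states[sub$cell_type == tp])
          flat <- unlist(sp)
          cnts <- vapply(fs, function(m) sum(flat == m), numeric(1))
          feats <- c(feats, paste0(pre, "|", comp, "|", level, "|",
                                   tp, ":", fs, "+"))
          vals <- c(vals, cnts / tot)
        }
        out[[length(out) + 1]] <- rec(pid, feats, vals)
      } else {
        lab <- phenotype_labels(sub, level, panel)
        tb <- table(lab) / tot
        phen <- if (level == "base") base_types else names(tb)
        v <- as.numeric(tb[phen]); v[is.na(v)] <- 0
        out[[length(out) + 1]] <- rec(pid,
          paste0(pre, "|", comp, "|", level, "|", phen), v)
      }
    }
  }
  do.call(rbind, out) %||% rec(character(), character(), numeric())[0, ]
}

#' Cell-count ratios between base types
#'
#' Ratio of cell counts for ordered pairs of base cell types within each
#' compartment of a view, per patient. A zero denominator yields a null
#' (NA) record which propagates to imputation.
#'
#' @param cells annotated cell table.
#' @param view `"cn2"`, `"cn3"` or `"mbn"`.
#' @param pairs list of `c(numerator, denominator)` type pairs, or `NULL`
#'   for all ordered pairs of types present in the cohort.
#' @param panel [panel_config()].
#' @return long data.frame (patient_id, feature, value).
#' @export
count_ratios <- function(cells, view = "cn2", pairs = NULL,
                         panel = default_panel()) {
  col <- view_column(view)
  keep <- cells$cell_type != "artifact" & !is.na(cells[[col]])
  cc <- cells[keep, , drop = FALSE]
  if (is.null(pairs)) {
    tys <- sort(unique(cc$cell_type))
    pairs <- list()
    for (a in tys) for (b in tys) if (a != b)
      pairs[[length(pairs) + 1]] <- c(a, b)
  }
  num <- vapply(pairs, `[`, "", 1)
  den <- vapply(pairs, `[`, "", 2)
  out <- list()
  for (pid in unique(cc$patient_id)) {
    pc <- cc[cc$patient_id == pid, , drop = FALSE]
    for (comp in unique(pc[[col]])) {
      tb <- table(pc$cell_type[pc[[col]] == comp])
      cnt <- function(t) {
        v <- as.numeric(tb[t]); v[is.na(v)] <- 0; v
      }
      dv <- cnt(den)
      vals <- ifelse(dv > 0, cnt(num) / dv, NA_real_)
      out[[length(out) + 1]] <- rec(pid,
        paste("ratio", view, comp, num, den, sep = "|"), vals)
    }
  }
  do.call(rbind, out) %||% rec(character(), character(), numeric())[0, ]
}

#' Spatial interaction features for a cohort
#'
#' Per patient/core and per compartment, computes G-cross AUC, JSD and
#' (optionally) permutation interaction z-scores for the requested
#' phenotype pairs, plus edge-cell G-cross between compartment boundary
#' point sets. Both point sets are restricted to the compartment. Null
#' metrics (empty sets) are emitted as NA records.
#'
#' @param cells annotated cell table.
#' @param views views to use (any of `"cn2"`, `"cn3"`, `"mbn"`).
#' @param pairs list of `c(ref, target)` base-type pairs, or `NULL` for all
#'   ordered pairs of the `top_types` most abundant types.
#' @param top_types bound on the number of types paired when `pairs` is
#'   `NULL`.
#' @param families subset of `c("gcross", "jsd", "intz", "gxedge")`.
#' @param r_max G-cross radius cap (µm).
#' @param intz_radius,intz_perm interaction-score radius and permutations.
#' @param seed RNG seed (interaction score nulls).
#' @param panel [panel_config()].
#' @return long data.frame (patient_id, feature, value).
#' @export
spatial_features <- function(cells, views = c("cn2", "cn3", "mbn"),
                             pairs = NULL, top_types = 6,
                             families = c("gcross", "jsd", "gxedge"),
                             r_max = 150, intz_radius = 100,
                             intz_perm = 50L, seed = 1L,
                             panel = default_panel()) {
  keep <- cells$cell_type != "artifact"
  cc <- cells[keep, , drop = FALSE]
  if (is.null(pairs)) {
    ab <- names(sort(table(cc$cell_type), decreasing = TRUE))
    ab <- head(ab, top_types)
    pairs <- list()
    for (a in ab) for (b in ab) if (a != b)
      pairs[[length(pairs) + 1]] <- c(a, b)
  }
  out <- list()
  pseed <- derive_seeds(seed, length(unique(cc$patient_id)))
  pi_ <- 0
  for (pid in unique(cc$patient_id)) {
    pi_ <- pi_ + 1
    pc <- cc[cc$patient_id == pid, , drop = FALSE]
    for (view in views) {
      col <- view_column(view)
      if (!col %in% names(pc)) next
      comps <- stats::na.omit(unique(pc[[col]]))
      for (comp in comps) {
        sub <- pc[!is.na(pc[[col]]) & pc[[col]] == comp, , drop = FALSE]
        types <- unique(unlist(pairs))
        sets <- lapply(types, function(t) as.matrix(
          sub[sub$cell_type == t, c("x_um", "y_um"), drop = FALSE]))
        names(sets) <- types
        for (pr in pairs) {
          A <- sets[[pr[1]]]; B <- sets[[pr[2]]]
          if ("gcross" %in% families)
            out[[length(out) + 1]] <- rec(pid,
              make_feature_name("gcross", view, comp, pr[1], pr[2]),
              gcross_auc(A, B, r_max = r_max)$auc)
          if ("intz" %in% families)
            out[[length(out) + 1]] <- rec(pid,
              make_feature_name("intz", view, comp, pr[1], pr[2]),
              interaction_zscore(
                sub[, c("x_um", "y_um")], sub$cell_type == pr[1],
                sub$cell_type == pr[2], radius = intz_radius,
                n_perm = intz_perm, seed = pseed[pi_])$z)
        }
        if ("jsd" %in% families) {
          # symmetric: one record per unordered pair; densities built once
          # per phenotype on a shared compartment grid
          up <- Filter(function(pr) pr[1] < pr[2], pairs)
          if (length(up)) {
            idx_pairs <- lapply(up, function(pr) match(pr, types))
            dvals <- jsd_matrix(sets, idx_pairs)
            for (k in seq_along(up))
              out[[length(out) + 1]] <- rec(pid,
                make_feature_name("jsd", view, comp, up[[k]][1],
                                  up[[k]][2]), dvals[k])
          }
        }
      }
      if ("gxedge" %in% families && view != "mbn" && length(comps) > 1) {
        ed <- edge_cells(pc, col)
        for (ca in comps) for (cb in comps) {
          if (ca == cb) next
          A <- as.matrix(pc[ed & !is.na(pc[[col]]) & pc[[col]] == ca,
                            c("x_um", "y_um"), drop = FALSE])
          B <- as.matrix(pc[ed & !is.na(pc[[col]]) & pc[[col]] == cb,
                            c("x_um", "y_um"), drop = FALSE])
          out[[length(out) + 1]] <- rec(pid,
            make_feature_name("gxedge", view, ca, cb, "all", "all"),
            gcross_auc(A, B, r_max = r_max)$auc)
        }
      }
    }
  }
  do.call(rbind, out) %||% rec(character(), character(), numeric())[0, ]
}

#' Assemble the patient x feature matrix
#'
#' Widens long feature records into a patient-by-feature matrix aligned to
#' the clinical table, applies the family-specific imputation (JSD nulls
#' become 1 — maximal separation — all other nulls become 0), drops
#' features with fewer than `min_unique` distinct raw values (nulls count
#' as one value; the filter runs before scaling), and standard-scales each
#' remaining column to mean 0 / sd 1, keeping the raw matrix alongside.
#'
#' @param records long data.frame(s) with `patient_id`, `feature`, `value`;
#'   a list is row-bound.
#' @param clinical clinical table defining patient order.
#' @param min_unique unique-value filter threshold.
#' @return object of class `feature_matrix`: `raw`, `scaled`, `family`
#'   (named by feature), `patients`, `dropped`.
#' @export
assemble_features <- function(records, clinical, min_unique = 25L) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  key <- paste(records$patient_id, records$feature)
  if (anyDuplicated(key))
    stopf("duplicate feature record: %s", key[duplicated(key)][1])
  patients <- clinical$patient_id
  feats <- sort(unique(records$feature))
  raw <- matrix(NA_real_, length(patients), length(feats),
                dimnames = list(patients, feats))
  raw[cbind(match(records$patient_id, patients),
            match(records$feature, feats))] <- records$value
  fam <- vapply(feats, feature_family, "")
  # unique-value filter on raw values, nulls counted as one value
  nuniq <- apply(raw, 2, function(v) length(unique(v)))
  keep <- nuniq >= min_unique
  dropped <- feats[!keep]
  raw <- raw[, keep, drop = FALSE]
  fam <- fam[keep]
  # family imputation
  is_jsd <- startsWith(colnames(raw), "jsd|")
  for (j in seq_len(ncol(raw))) {
    nas <- is.na(raw[, j])
    if (any(nas)) raw[nas, j] <- if (is_jsd[j]) 1 else 0
  }
  mu <- colMeans(raw)
  sdv <- apply(raw, 2, sd)
  sdv[sdv == 0] <- 1
  scaled <- sweep(sweep(raw, 2, mu), 2, sdv, "/")
  structure(list(raw = raw, scaled = scaled, family = fam,
                 patients = patients, center = mu, scale = sdv,
                 dropped = dropped),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d patients x %d features (%d dropped by unique-value filter)\n",
              nrow(x$raw), ncol(x$raw), length(x$dropped)))
  tb <- sort(table(x$family), decreasing = TRUE)
  for (nm in names(tb)) cat(sprintf("  %-24s %d\n", nm, tb[[nm]]))
  invisible(x)
}

#' Write a feature matrix (wide CSV + feature dictionary)
#' @param fm `feature_matrix`.
#' @param path base path; writes `<path>.csv` (raw values) and
#'   `<path>_dictionary.csv` (feature, family).
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(patient_id = fm$patients, fm$raw, check.names = FALSE)
  write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  write.csv(data.frame(feature = colnames(fm$raw), family = fm$family),
            paste0(path, "_dictionary.csv"), row.names = FALSE)
  invisible(path)
}
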