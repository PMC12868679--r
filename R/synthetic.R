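#' Synthetic TMA cohort configuration
#'
#' Builds the configuration for the synthetic tissue-microarray generator.
#' Each patient contributes one circular core (default radius 300 µm, the
#' scale of a 600 µm TMA punch) containing tumor cells concentrated in
#' Gaussian nests over a background Poisson process of stromal and immune
#' cells. Metabolic marker positivity decays from nest centres into the
#' stroma, creating spatially structured metabolic neighbourhoods, and
#' survival outcomes are drawn from an exponential-baseline Cox model with
#' planted effects on patient-level spatial features.
#'
#' Default cell-type frequencies follow reported NSCLC TMA compositions
#' (tumor 41.4%, macrophages 14%, CD4 T cells 8.6%, CD8 T cells 4.5%,
#' immune NOS 3%, granulocytes 2.5%, CD4 Tregs 1.9%, plasma cells 1.7%,
#' B cells 1.6%, myeloid NOS 1.3%), with the stromal remainder split over
#' fibroblasts, myofibroblasts, endothelial cells and an "other" class.
#'
#' @param n_patients number of patients (one core each).
#' @param core_radius core radius in µm.
#' @param cells_per_core integer range `c(min, max)` of cells per core.
#' @param n_tumor_nests number of Gaussian tumor nests per core.
#' @param nest_radius nest scale (µm); must be below `core_radius`.
#' @param nest_exclusion probability that a non-tumor cell falling inside a
#'   nest is displaced into the stroma — tumor nests largely exclude
#'   stromal and immune cells, with partial immune infiltration.
#' @param cell_type_freqs named proportions summing to 1 over the panel's
#'   cell types.
#' @param marker_cond_probs nested list `type -> marker -> probability` of
#'   functional-marker positivity conditional on cell type.
#' @param metabolic_gradient named list `pathway -> c(center, edge)`
#'   positivity probabilities at nest centre / deep stroma.
#' @param metabolic_levels optional integer: discretize the nest-proximity
#'   weight into this many bands, recording the band as planted ground truth
#'   (`true_metabolic_level`). `NULL` keeps the smooth gradient.
#' @param planted_effects list of `list(feature =, beta =)` entries; see
#'   [planted_feature_descriptors()].
#' @param censor_rate target fraction of censored PFS times.
#' @param median_pfs baseline median progression-free survival (months).
#' @param artifact_rate fraction of cells given the artifact profile.
#' @param seed integer; fully determines the cohort.
#' @param panel [panel_config()]; defaults to [default_panel()].
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 60,
                             core_radius = 300,
                             cells_per_core = c(1500, 2500),
                             n_tumor_nests = 3,
                             nest_radius = 80,
                             nest_exclusion = 0.8,
                             cell_type_freqs = NULL,
                             marker_cond_probs = NULL,
                             metabolic_gradient = NULL,
                             metabolic_levels = NULL,
                             planted_effects = list(),
                             censor_rate = 0.3,
                             median_pfs = 12,
                             artifact_rate = 0,
                             seed = 1L,
                             panel = default_panel()) {
  if (nest_radius >= core_radius)
    stopf("nest_radius (%g) must be smaller than core_radius (%g)",
          nest_radius, core_radius)
  if (is.null(cell_type_freqs)) cell_type_freqs <- default_type_freqs()
  if (abs(sum(cell_type_freqs) - 1) > 1e-9)
    stopf("cell_type_freqs must sum to 1 (got %.12f)", sum(cell_type_freqs))
  bad <- setdiff(names(cell_type_freqs), panel_cell_types(panel))
  if (length(bad)) stopf("unknown cell type in freqs: %s", bad[1])
  if (is.null(marker_cond_probs))
    marker_cond_probs <- default_marker_cond_probs(panel)
  if (is.null(metabolic_gradient))
    metabolic_gradient <- default_metabolic_gradient()
  for (p in metabolic_gradient)
    if (any(p < 0 | p > 1)) stopf("metabolic gradient levels must be in [0,1]")
  known <- planted_feature_descriptors()
  for (eff in planted_effects)
    if (!eff$feature %in% known)
      stopf("unrecognized planted feature descriptor '%s'", eff$feature)
  structure(list(
    n_patients = as.integer(n_patients), core_radius = core_radius,
    cells_per_core = as.integer(cells_per_core),
    n_tumor_nests = as.integer(n_tumor_nests), nest_radius = nest_radius,
    nest_exclusion = nest_exclusion,
    cell_type_freqs = cell_type_freqs,
    marker_cond_probs = marker_cond_probs,
    metabolic_gradient = metabolic_gradient,
    metabolic_levels = metabolic_levels,
    planted_effects = planted_effects,
    censor_rate = censor_rate, median_pfs = median_pfs,
    artifact_rate = artifact_rate,
    seed = as.integer(seed), panel = panel
  ), class = "synthetic_config")
}

default_type_freqs <- function() {
  c("tumor" = 0.414, "macrophage" = 0.14, "myeloid NOS" = 0.013,
    "immune NOS" = 0.03, "granulocyte" = 0.025, "B cell" = 0.016,
    "plasma cell" = 0.017, "CD4 Treg" = 0.019, "CD4 T cell" = 0.086,
    "CD8 T cell" = 0.045, "fibroblast" = 0.08, "myofibroblast" = 0.04,
    "endothelial" = 0.05, "other" = 0.025)
}

default_marker_cond_probs <- function(panel) {
  tum <- c(PDL1 = 0.25, Vimentin = 0.2, Ki67 = 0.3, IDO1 = 0.15,
           "HLA-A" = 0.5)
  imm <- c(PD1 = 0.2, PDL1 = 0.15, GranzymeB = 0.2, ICOS = 0.15,
           IDO1 = 0.1)
  out <- list()
  for (tp in panel_cell_types(panel)) {
    out[[tp]] <- if (tp %in% panel$tumor_types) tum else imm
  }
  # lineage-specific tweaks: cytotoxic cells richer in granzyme B
  out[["CD8 T cell"]]["GranzymeB"] <- 0.35
  out[["macrophage"]]["GranzymeB"] <- 0.25
  out[["CD4 Treg"]][c("PD1", "ICOS")] <- c(0.35, 0.4)
  out
}

default_metabolic_gradient <- function() {
  list(Glycolysis      = c(0.75, 0.15),
       ATPSynthesis    = c(0.65, 0.20),
       TCACycle        = c(0.60, 0.20),
       AminoAcidUptake = c(0.50, 0.15),
       PPP             = c(0.40, 0.15),
       FAOxidation     = c(0.35, 0.10),
       OxRegulatory    = c(0.30, 0.10))
}

#' Recognized planted-effect feature descriptors
#'
#' Patient-level latent quantities the generator can couple to the hazard:
#' \describe{
#'   \item{gzmb_macrophage_fraction}{the patient's latent granzyme-B
#'     positivity rate among macrophages (logit-normal across patients).}
#'   \item{tumor_fraction}{the patient's latent tumor-cell proportion.}
#'   \item{glycolysis_center_level}{the patient's glycolysis positivity
#'     level at nest centres.}
#' }
#' @return character vector of descriptor names.
#' @export
planted_feature_descriptors <- function() {
  c("gzmb_macrophage_fraction", "tumor_fraction",
    "glycolysis_center_level")
}

# per-patient latent draws for every recognized descriptor
draw_patient_latents <- function(config, n) {
  base_gzmb <- config$marker_cond_probs[["macrophage"]][["GranzymeB"]]
  base_tum <- config$cell_type_freqs[["tumor"]]
  base_gly <- config$metabolic_gradient$Glycolysis[1]
  data.frame(
    gzmb_macrophage_fraction =
      stats::plogis(stats::qlogis(base_gzmb) + rnorm(n, 0, 0.9)),
    tumor_fraction =
      stats::plogis(stats::qlogis(base_tum) + rnorm(n, 0, 0.35)),
    glycolysis_center_level =
      stats::plogis(stats::qlogis(base_gly) + rnorm(n, 0, 0.5))
  )
}

core_seed_for <- function(config, patient_id) {
  h <- sum(utf8ToInt(as.character(patient_id)) *
             seq_along(utf8ToInt(as.character(patient_id))))
  as.integer((as.numeric(config$seed) * 7919 + h * 131) %% 2147483646) + 1L
}

#' Generate one synthetic TMA core
#'
#' Tumor cells are placed in isotropic Gaussian nests (sd = `nest_radius`/2,
#' truncated to the core disc); all other cells form a uniform background in
#' the disc. Lineage marker positivity follows the panel's rule profile
#' exactly; functional markers are Bernoulli draws conditional on cell type;
#' metabolic markers interpolate between nest-centre and stromal positivity
#' levels through a Gaussian kernel in the distance to the nearest nest
#' centre. Marker probabilities are Beta draws concentrated near 1 for
#' positive and near 0 for negative cells.
#'
#' Ground-truth columns (`true_region`, `true_nest_dist`,
#' `true_metabolic_level`) are carried for validation against planted
#' structure.
#'
#' @param config [synthetic_config()].
#' @param patient_id patient identifier; also seeds the core.
#' @param latents optional one-row data frame of patient latent values
#'   (see [planted_feature_descriptors()]); drawn internally when omitted.
#' @return a `cell_table` data frame for one core.
#' @export
generate_core <- function(config, patient_id, latents = NULL) {
  with_seed(core_seed_for(config, patient_id), {
    if (is.null(latents)) latents <- draw_patient_latents(config, 1)
    panel <- config$panel
    R <- config$core_radius
    n <- if (config$cells_per_core[1] == config$cells_per_core[2])
      config$cells_per_core[1]
    else sample(config$cells_per_core[1]:config$cells_per_core[2], 1)

    freqs <- config$cell_type_freqs
    freqs["tumor"] <- freqs[["tumor"]] *
      latents$tumor_fraction / config$cell_type_freqs[["tumor"]]
    if (config$n_tumor_nests == 0L) freqs["tumor"] <- 0
    freqs <- freqs / sum(freqs)
    types <- sample(names(freqs), n, replace = TRUE, prob = freqs)

    # nest centres inside the inner 60% of the disc
    k <- max(config$n_tumor_nests, 1L)
    th <- runif(k, 0, 2 * pi); rr <- 0.6 * R * sqrt(runif(k))
    nests <- cbind(rr * cos(th), rr * sin(th))

    x <- y <- numeric(n)
    in_nest <- function(px, py) {
      if (config$n_tumor_nests == 0L) return(FALSE)
      any((px - nests[seq_len(config$n_tumor_nests), 1])^2 +
            (py - nests[seq_len(config$n_tumor_nests), 2])^2 <=
            config$nest_radius^2)
    }
    bg <- which(types != "tumor")
    for (i in bg) {
      repeat {
        thb <- runif(1, 0, 2 * pi); rb <- R * sqrt(runif(1))
        px <- rb * cos(thb); py <- rb * sin(thb)
        # nests mostly exclude stromal/immune cells
        if (!in_nest(px, py) || runif(1) > config$nest_exclusion) break
      }
      x[i] <- px; y[i] <- py
    }
    tu <- which(types == "tumor")
    if (length(tu)) {
      nid <- sample.int(config$n_tumor_nests, length(tu), replace = TRUE)
      sdn <- config$nest_radius / 2
      for (i in seq_along(tu)) {
        # isotropic Gaussian truncated to the nest disc (and the core)
        repeat {
          px <- rnorm(1, nests[nid[i], 1], sdn)
          py <- rnorm(1, nests[nid[i], 2], sdn)
          d2n <- (px - nests[nid[i], 1])^2 + (py - nests[nid[i], 2])^2
          if (px * px + py * py < R * R &&
                d2n <= config$nest_radius^2) break
        }
        x[tu[i]] <- px; y[tu[i]] <- py
      }
    }
    nest_dist <- rep(Inf, n)
    if (config$n_tumor_nests > 0) {
      d2 <- matrix(Inf, n, config$n_tumor_nests)
      for (j in seq_len(config$n_tumor_nests))
        d2[, j] <- (x - nests[j, 1])^2 + (y - nests[j, 2])^2
      nest_dist <- sqrt(apply(d2, 1, min))
    }

    cells <- data.frame(
      core_id = paste0("core_", patient_id),
      patient_id = as.character(patient_id),
      cell_id = sprintf("c%05d", seq_len(n)),
      x_um = x - min(x), y_um = y - min(y),
      true_type = types,
      true_region = ifelse(nest_dist <= config$nest_radius, "nest", "stroma"),
      true_nest_dist = nest_dist,
      stringsAsFactors = FALSE
    )

    # lineage positivity: exact rule profile of the true type
    rules <- panel$phenotype_rules
    names(rules) <- vapply(rules, `[[`, "", "type")
    for (m in panel$lineage_markers)
      cells[[pos_cols(m)]] <- logical(n)
    for (tp in unique(types)) {
      idx <- which(types == tp)
      for (m in rules[[tp]]$pos) cells[[pos_cols(m)]][idx] <- TRUE
    }
    if (config$artifact_rate > 0 && length(panel$artifact_rules)) {
      art <- which(runif(n) < config$artifact_rate)
      if (length(art)) {
        for (m in panel$lineage_markers) cells[[pos_cols(m)]][art] <- FALSE
        for (m in panel$artifact_rules[[1]]$pos)
          cells[[pos_cols(m)]][art] <- TRUE
        cells$true_type[art] <- "artifact"
      }
    }

    # functional markers: Bernoulli given type, patient-modified gzmb rate
    cond <- config$marker_cond_probs
    for (tp in names(cond))
      if ("GranzymeB" %in% names(cond[[tp]]) && tp == "macrophage")
        cond[[tp]]["GranzymeB"] <- latents$gzmb_macrophage_fraction
    for (m in panel$functional_markers)
      if (!pos_cols(m) %in% names(cells)) cells[[pos_cols(m)]] <- logical(n)
    for (tp in unique(cells$true_type)) {
      if (tp == "artifact") next
      idx <- which(cells$true_type == tp)
      pr <- cond[[tp]]
      for (m in intersect(names(pr), panel$functional_markers))
        cells[[pos_cols(m)]][idx] <- runif(length(idx)) < pr[[m]]
    }

    # metabolic markers: gradient in distance to nearest nest centre
    w <- exp(-nest_dist^2 / (2 * config$nest_radius^2))
    if (!is.null(config$metabolic_levels)) {
      # discrete rings of width nest_radius around the nearest nest centre;
      # innermost ring = highest level
      L <- as.integer(config$metabolic_levels)
      ring <- pmin(L - 1L, floor(nest_dist / config$nest_radius))
      lev <- L - ring                      # L (centre) .. 1 (deep stroma)
      w <- (lev - 1) / (L - 1)
      cells$true_metabolic_level <- as.integer(lev)
    }
    grad <- config$metabolic_gradient
    grad$Glycolysis[1] <- latents$glycolysis_center_level
    for (pw in names(grad)) {
      m <- panel$pathway_map[[pw]]
      p <- grad[[pw]][2] + (grad[[pw]][1] - grad[[pw]][2]) * w
      cells[[pos_cols(m)]] <- runif(n) < p
    }

    # probabilities consistent with the binary calls
    for (m in panel_markers(panel)) {
      pos <- cells[[pos_cols(m)]]
      pr <- numeric(n)
      pr[pos] <- rbeta(sum(pos), 14, 3)
      pr[!pos] <- rbeta(sum(!pos), 1.2, 12)
      cells[[prob_cols(m)]] <- pr
    }
    validate_cell_table(cells, panel)
    cells
  })
}

#' Generate a full synthetic cohort
#'
#' Draws per-patient latent feature values, generates one core per patient,
#' and simulates survival from a Cox model with exponential baseline:
#' linear predictor \eqn{\eta_i = \sum_k \beta_k z_{ik}} over the planted
#' effects (z = cohort-standardized latent value), PFS hazard
#' \eqn{\lambda_0 e^{\eta_i}} with \eqn{\lambda_0 = \log 2 / } `median_pfs`,
#' independent exponential censoring calibrated to `censor_rate`, and OS
#' generated with attenuated effect (0.7 η) and half the baseline hazard.
#' Best overall response is assigned from PFS quartiles (longest quartile
#' CR, then PR, SD, PD) so that the CB6 rule is consistent with PFS.
#'
#' @param config [synthetic_config()].
#' @return list with elements `cells` (row-bound cell tables), `clinical`
#'   (clinical table with `cb6`), and `truth` (per-patient latent feature
#'   values and linear predictor).
#' @export
generate_cohort <- function(config) {
  n <- config$n_patients
  pids <- sprintf("P%03d", seq_len(n))
  latents <- with_seed(config$seed, draw_patient_latents(config, n))

  eta <- rep(0, n)
  for (eff in config$planted_effects) {
    z <- as.numeric(scale(latents[[eff$feature]]))
    eta <- eta + eff$beta * z
  }

  cells <- vector("list", n)
  for (i in seq_len(n))
    cells[[i]] <- generate_core(config, pids[i], latents[i, , drop = FALSE])
  cells <- do.call(rbind, cells)

  clinical <- with_seed(config$seed + 1L, {
    lam0 <- log(2) / config$median_pfs
    t_pfs <- rexp(n, lam0 * exp(eta))
    if (config$censor_rate > 0) {
      lam_c <- lam0 * config$censor_rate / (1 - config$censor_rate)
      cens <- rexp(n, lam_c)
    } else cens <- rep(Inf, n)
    pfs_time <- pmin(t_pfs, cens)
    pfs_event <- t_pfs <= cens
    t_os <- t_pfs + rexp(n, 2 * lam0 * exp(0.7 * eta))
    os_time <- pmin(t_os, ifelse(is.finite(cens), cens * 2, Inf))
    os_event <- t_os <= ifelse(is.finite(cens), cens * 2, Inf)
    q <- rank(t_pfs, ties.method = "first") / n
    bor <- cut(q, c(0, 0.25, 0.5, 0.75, 1),
               labels = c("PD", "SD", "PR", "CR"))
    data.frame(patient_id = pids,
               cohort_id = ifelse(seq_len(n) %% 2 == 0, "TMA_A", "TMA_B"),
               pfs_time = pfs_time, pfs_event = pfs_event,
               os_time = os_time, os_event = os_event,
               bor = as.character(bor), stringsAsFactors = FALSE)
  })
  clinical <- derive_cb6(clinical)
  truth <- cbind(data.frame(patient_id = pids), latents,
                 linear_predictor = eta)
  list(cells = cells, clinical = clinical, truth = truth)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic TMA cohort configuration\n")
  cat(sprintf("  patients: %d, core radius %g um, %d-%d cells/core\n",
              x$n_patients, x$core_radius, x$cells_per_core[1],
              x$cells_per_core[2]))
  cat(sprintf("  tumor nests: %d (radius %g um)\n", x$n_tumor_nests,
              x$nest_radius))
  cat(sprintf("  planted effects: %d, censor rate %.2f, seed %d\n",
              length(x$planted_effects), x$censor_rate, x$seed))
  invisible(x)
}
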