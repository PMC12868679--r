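#' Pipeline configuration
#'
#' A single YAML (or list) drives the end-to-end run. Top-level keys:
#' `out_dir`, `seed`, and either `synthetic:` (arguments to
#' [synthetic_config()]) or `inputs: {cells: path, clinical: path}`;
#' optional `neighborhoods`, `metrics`, `features`, `selection`,
#' `survival` blocks override stage defaults.
#'
#' @param path YAML file path.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  cfg$out_dir <- NULL  # relocating outputs must not invalidate the cache
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}

stage_path <- function(out_dir, name) file.path(out_dir, name)

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> phenotype -> neighbourhoods -> spatial
#' metrics + proportions -> feature assembly -> stability selection ->
#' survival modelling, writing each stage's artifact CSVs under
#' `out_dir` and a JSON run manifest. When `resume = TRUE` and the stored
#' manifest carries the same config hash, completed stages are reloaded
#' from their artifacts instead of recomputed, and the final outputs are
#' identical to a full run.
#'
#' @param config config list or YAML path ([read_pipeline_config()]).
#' @param resume reuse cached stage outputs when the config hash matches.
#' @param verbose log stage progress to stderr.
#' @return (invisibly) list with `manifest` and the stage results
#'   (`cells`, `clinical`, `nbhd_models`, `features`, `selection`,
#'   `survival`).
#' @export
run_pipeline <- function(config, resume = FALSE, verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- config$out_dir %||% stopf("config needs out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  seeds <- derive_seeds(seed, 6)
  hash <- config_hash(config)
  man_path <- file.path(out_dir, "manifest.json")
  cached_ok <- FALSE
  if (resume && file.exists(man_path)) {
    old <- jsonlite::read_json(man_path)
    cached_ok <- identical(old$config_hash[[1]], unname(hash))
  }
  manifest <- list(config_hash = unname(hash), seed = seed,
                   stages = list(), warnings = character())
  panel <- if (!is.null(config$panel)) read_panel_config(config$panel)
           else default_panel()

  timed <- function(name, loader, runner) {
    t0 <- proc.time()[3]
    cached <- FALSE
    res <- NULL
    if (cached_ok && !is.null(loader)) {
      res <- tryCatch(suppressWarnings(loader()),
                      error = function(e) NULL)
      cached <- !is.null(res)
    }
    if (is.null(res)) res <- runner()
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[3] - t0, 2),
                                     cached = cached)
    msg("[%s] done in %.1fs%s", name, proc.time()[3] - t0,
        if (cached) " (cached)" else "", verbose = verbose)
    res
  }

  # -- stage 1: cohort ------------------------------------------------------
  cells_csv <- stage_path(out_dir, "cells_raw.csv")
  clin_csv <- stage_path(out_dir, "clinical.csv")
  cohort <- timed("simulate",
    loader = function() list(cells = read_cell_table(cells_csv, panel),
                             clinical = read_clinical_table(clin_csv)),
    runner = function() {
      if (!is.null(config$inputs)) {
        co <- list(cells = read_cell_table(config$inputs$cells, panel),
                   clinical = read_clinical_table(config$inputs$clinical))
      } else {
        sc_args <- config$synthetic %||% list()
        sc_args$seed <- sc_args$seed %||% seeds[1]
        sc_args$panel <- panel
        if (!is.null(sc_args$planted_effects))
          sc_args$planted_effects <- lapply(sc_args$planted_effects,
                                            as.list)
        sc <- do.call(synthetic_config, sc_args)
        co <- generate_cohort(sc)
        write_clinical_table(co$clinical, clin_csv)
        utils::write.csv(co$truth, stage_path(out_dir, "truth.csv"),
                         row.names = FALSE)
      }
      write_cell_table(co$cells, cells_csv)
      co
    })
  clinical <- derive_cb6(cohort$clinical)

  # -- stage 2: phenotyping -------------------------------------------------
  pheno_csv <- stage_path(out_dir, "cells_phenotyped.csv")
  cells <- timed("phenotype",
    loader = function() read_cell_table(pheno_csv, panel),
    runner = function() {
      ph <- phenotype_cells(cohort$cells, panel)
      if (!is.null(ph$thresholds))
        write_thresholds(ph$thresholds,
                         stage_path(out_dir, "thresholds.yaml"))
      write_cell_table(ph$cells, pheno_csv)
      ph$cells
    })

  # -- stage 3: neighbourhoods ---------------------------------------------
  nb_csv <- stage_path(out_dir, "cells_neighborhoods.csv")
  nb_cfg <- config$neighborhoods %||% list()
  nb <- timed("neighborhoods",
    loader = function() list(cells = read_cell_table(nb_csv, panel),
                             models = NULL),
    runner = function() {
      res <- annotate_neighborhoods(
        cells, panel, seed = seeds[2],
        windows = modifyList(list(cn2 = 50, cn3 = 30, mbn = 30),
                             nb_cfg$windows %||% list()))
      for (v in names(res$models))
        write_nbhd_model(res$models[[v]],
                         stage_path(out_dir, paste0("nbhd_", v)))
      write_cell_table(res$cells, nb_csv)
      res
    })
  cells <- nb$cells

  # -- stage 4: metrics + proportions --------------------------------------
  met_csv <- stage_path(out_dir, "features_long.csv")
  mcfg <- config$metrics %||% list()
  records <- timed("metrics",
    loader = function() read.csv(met_csv, stringsAsFactors = FALSE),
    runner = function() {
      views <- mcfg$views %||% c("cn2", "cn3", "mbn")
      recs <- list()
      for (v in views) {
        for (lv in (mcfg$levels %||% c("base", "functional", "metabolic")))
          recs[[length(recs) + 1]] <-
            compartment_proportions(cells, v, lv, panel)
        if (v != "mbn")
          recs[[length(recs) + 1]] <- count_ratios(cells, v, panel = panel)
      }
      recs[[length(recs) + 1]] <- spatial_features(
        cells, views = views,
        pairs = mcfg$pairs,
        top_types = mcfg$top_types %||% 6,
        families = mcfg$families %||% c("gcross", "jsd", "gxedge"),
        intz_perm = mcfg$intz_perm %||% 50L,
        seed = seeds[3], panel = panel)
      recs <- do.call(rbind, recs)
      write.csv(full_precision(recs), met_csv, row.names = FALSE)
      recs
    })

  # -- stage 5: feature matrix ---------------------------------------------
  fm <- timed("features", loader = NULL, runner = function() {
    f <- assemble_features(records, clinical,
                           min_unique = config$features$min_unique %||% 25L)
    write_feature_matrix(f, stage_path(out_dir, "feature_matrix"))
    f
  })

  # -- stage 6: stability selection ----------------------------------------
  scfg_in <- config$selection %||% list()
  sel <- timed("select", loader = NULL, runner = function() {
    scfg <- selection_config(
      n_subsamples = scfg_in$n_subsamples %||% 50L,
      decoy_mode = scfg_in$decoy_mode %||% "permutation",
      fdp_cap = scfg_in$fdp_cap %||% 0.5,
      endpoint = scfg_in$endpoint %||% "binary",
      grouped = isTRUE(scfg_in$grouped),
      seed = seeds[4])
    outcome <- if (scfg$endpoint == "cox")
      data.frame(time = clinical$pfs_time, event = clinical$pfs_event)
    else as.numeric(clinical$cb6)
    s <- select_features_by_family(fm, outcome, scfg,
                                   cohort = clinical$cohort_id)
    write_selection(s, stage_path(out_dir, "selection.csv"))
    s
  })

  # -- stage 7: survival ----------------------------------------------------
  surv <- timed("survive", loader = NULL, runner = function() {
    feats <- sel$selected
    if (!length(feats)) {
      manifest$warnings <<- c(manifest$warnings,
                              "no features selected; survival stage skipped")
      return(NULL)
    }
    Xs <- fm$scaled[, feats, drop = FALSE]
    cv <- kfold_cox_auc(Xs, clinical$pfs_time, clinical$pfs_event,
                        k = config$survival$k %||% 10L,
                        horizon = config$survival$horizon %||% 24,
                        seed = seeds[5])
    write.csv(cv$auc, stage_path(out_dir, "auc_pfs.csv"),
              row.names = FALSE)
    write.csv(cv$features, stage_path(out_dir, "cox_features.csv"),
              row.names = FALSE)
    pg <- prognosis_score(cv, Xs, clinical$pfs_time, clinical$pfs_event)
    write.csv(data.frame(patient_id = clinical$patient_id,
                         prognosis_score = pg$score),
              stage_path(out_dir, "prognosis_scores.csv"),
              row.names = FALSE)
    list(cv = cv, prognosis = pg)
  })

  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, cells = cells, clinical = clinical,
                 nbhd_models = nb$models, features = fm, selection = sel,
                 survival = surv))
}
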