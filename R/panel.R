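#' Panel configuration
#'
#' A `panel_config` describes the marker panel and the rule table that turns
#' binary marker positivity into mutually exclusive cell types. Markers play
#' one of three roles: lineage markers drive the phenotype rules, functional
#' markers describe activation states, and metabolic markers are per-pathway
#' proxies (one marker per pathway).
#'
#' Phenotype rules are an ordered list; each rule names the lineage markers
#' that must be positive (`pos`) and those that must be negative (`neg`).
#' A cell matches a rule when all `pos` markers are positive and all `neg`
#' markers are negative; markers mentioned in neither set are unconstrained.
#' The first matching rule wins, so earlier rules take precedence. Artifact
#' rules use the same structure; cells matching an artifact rule are labelled
#' `"artifact"` and excluded downstream.
#'
#' @param lineage_markers,functional_markers,metabolic_markers character
#'   vectors of marker names.
#' @param phenotype_rules ordered list of `list(type=, pos=, neg=)` entries.
#' @param artifact_rules list of `list(pos=, neg=)` entries (may be empty).
#' @param pathway_map named character vector mapping exactly 7 metabolic
#'   pathways to their proxy marker.
#' @param tumor_functional_set,immune_functional_set functional markers
#'   admissible for tumor and non-tumor cells respectively.
#' @param tumor_types cell types counted as tumor for the binary
#'   tumor/non-tumor neighbourhood basis.
#' @return an object of class `panel_config`.
#' @export
panel_config <- function(lineage_markers, functional_markers,
                         metabolic_markers, phenotype_rules,
                         artifact_rules = list(), pathway_map,
                         tumor_functional_set, immune_functional_set,
                         tumor_types = "tumor") {
  pc <- structure(list(
    lineage_markers = as.character(lineage_markers),
    functional_markers = as.character(functional_markers),
    metabolic_markers = as.character(metabolic_markers),
    phenotype_rules = phenotype_rules,
    artifact_rules = artifact_rules,
    pathway_map = pathway_map,
    tumor_functional_set = as.character(tumor_functional_set),
    immune_functional_set = as.character(immune_functional_set),
    tumor_types = as.character(tumor_types)
  ), class = "panel_config")
  validate_panel(pc)
  pc
}

validate_panel <- function(pc) {
  if (length(pc$pathway_map) != 7L)
    stopf("pathway_map must have exactly 7 entries, got %d",
          length(pc$pathway_map))
  types <- vapply(pc$phenotype_rules, `[[`, "", "type")
  if (anyDuplicated(types))
    stopf("duplicate rule target type: %s", types[duplicated(types)][1])
  all_markers <- panel_markers(pc)
  for (r in c(pc$phenotype_rules, pc$artifact_rules)) {
    ref <- c(r$pos, r$neg)
    bad <- setdiff(ref, all_markers)
    if (length(bad))
      stopf("rule references unknown marker(s): %s",
            paste(bad, collapse = ", "))
  }
  if (!all(pc$pathway_map %in% all_markers))
    stopf("pathway_map references markers outside the panel")
  invisible(pc)
}

panel_markers <- function(pc) {
  unique(c(pc$lineage_markers, pc$functional_markers, pc$metabolic_markers))
}

panel_cell_types <- function(pc) {
  vapply(pc$phenotype_rules, `[[`, "", "type")
}

#' @export
print.panel_config <- function(x, ...) {
  cat("Marker panel configuration\n")
  cat(sprintf("  lineage markers:    %d\n", length(x$lineage_markers)))
  cat(sprintf("  functional markers: %d\n", length(x$functional_markers)))
  cat(sprintf("  metabolic markers:  %d (7 pathway proxies)\n",
              length(x$metabolic_markers)))
  cat(sprintf("  phenotype rules:    %d types (+%d artifact rule%s)\n",
              length(x$phenotype_rules), length(x$artifact_rules),
              if (length(x$artifact_rules) == 1) "" else "s"))
  invisible(x)
}

#' Default NSCLC-style marker panel
#'
#' A 14-type panel modelled on multiplexed immunofluorescence studies of the
#' lung tumor microenvironment: epithelial tumor cells, myeloid and lymphoid
#' immune lineages, stromal/vascular cells and an all-negative "other" class,
#' plus five tumor / five immune functional markers and seven metabolic
#' pathway proxy markers (amino-acid uptake: ASCT2; ATP synthesis: ATPA5;
#' TCA cycle: citrate synthase CS; fatty-acid oxidation: CPT1A; pentose
#' phosphate pathway: G6PD; glycolysis: GLUT1; oxidative-stress regulation:
#' pNRF2).
#'
#' @return a [panel_config()] object.
#' @export
default_panel <- function() {
  lineage <- c("PanCK", "ECadherin", "CD45", "CD3", "CD4", "CD8", "FOXP3",
               "CD20", "CD14", "CD68", "CD31", "CD34", "CD11b", "Vimentin",
               "SMA")
  functional <- c("PD1", "PDL1", "GranzymeB", "ICOS", "IDO1", "Ki67",
                  "HLA-A")
  metabolic <- c("ASCT2", "ATPA5", "CS", "CPT1A", "G6PD", "GLUT1", "pNRF2")
  rules <- list(
    list(type = "tumor",         pos = c("PanCK", "ECadherin"), neg = "CD45"),
    list(type = "macrophage",    pos = c("CD45", "CD14", "CD68"), neg = character()),
    list(type = "myeloid NOS",   pos = c("CD45", "CD14"), neg = "CD68"),
    list(type = "CD4 Treg",      pos = c("CD45", "CD3", "CD4", "FOXP3"), neg = character()),
    list(type = "CD4 T cell",    pos = c("CD45", "CD3", "CD4"), neg = "FOXP3"),
    list(type = "CD8 T cell",    pos = c("CD45", "CD3", "CD8"), neg = character()),
    list(type = "B cell",        pos = c("CD45", "CD20"), neg = "CD3"),
    list(type = "plasma cell",   pos = c("CD45", "CD31"), neg = c("CD3", "CD20", "CD14")),
    list(type = "granulocyte",   pos = c("CD45", "CD11b"), neg = c("CD3", "CD14")),
    list(type = "immune NOS",    pos = "CD45",
         neg = c("CD3", "CD14", "CD20", "CD11b", "CD31")),
    list(type = "endothelial",   pos = c("CD31", "CD34"), neg = "CD45"),
    list(type = "fibroblast",    pos = "Vimentin",
         neg = c("CD45", "PanCK", "SMA", "CD31")),
    list(type = "myofibroblast", pos = "SMA", neg = c("CD45", "PanCK")),
    list(type = "other",         pos = character(), neg = lineage)
  )
  artifact <- list(
    # recurrent implausible co-positivity pattern treated as a staining artifact
    list(pos = c("PanCK", "CD45", "CD3", "CD20"), neg = character())
  )
  pathway_map <- c("AminoAcidUptake" = "ASCT2",
                   "ATPSynthesis"    = "ATPA5",
                   "TCACycle"        = "CS",
                   "FAOxidation"     = "CPT1A",
                   "PPP"             = "G6PD",
                   "Glycolysis"      = "GLUT1",
                   "OxRegulatory"    = "pNRF2")
  panel_config(
    lineage_markers = lineage,
    functional_markers = functional,
    metabolic_markers = metabolic,
    phenotype_rules = rules,
    artifact_rules = artifact,
    pathway_map = pathway_map,
    tumor_functional_set = c("PDL1", "Vimentin", "Ki67", "IDO1", "HLA-A"),
    immune_functional_set = c("PD1", "PDL1", "GranzymeB", "ICOS", "IDO1"),
    tumor_types = "tumor"
  )
}

#' Read / write a panel configuration as YAML
#'
#' @param path file path.
#' @rdname panel_io
#' @export
read_panel_config <- function(path) {
  y <- yaml::read_yaml(path)
  norm_rule <- function(r) {
    r$pos <- as.character(unlist(r$pos))
    r$neg <- as.character(unlist(r$neg))
    r
  }
  panel_config(
    lineage_markers = unlist(y$lineage_markers),
    functional_markers = unlist(y$functional_markers),
    metabolic_markers = unlist(y$metabolic_markers),
    phenotype_rules = lapply(y$phenotype_rules, norm_rule),
    artifact_rules = lapply(y$artifact_rules %||% list(), norm_rule),
    pathway_map = unlist(y$pathway_map),
    tumor_functional_set = unlist(y$tumor_functional_set),
    immune_functional_set = unlist(y$immune_functional_set),
    tumor_types = unlist(y$tumor_types %||% "tumor")
  )
}

#' @param panel a `panel_config`.
#' @rdname panel_io
#' @export
write_panel_config <- function(panel, path) {
  obj <- unclass(panel)
  obj$pathway_map <- as.list(obj$pathway_map)
  yaml::write_yaml(obj, path)
  invisible(path)
}
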