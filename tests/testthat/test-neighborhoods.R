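test_that("composition histograms count neighbours correctly", {
  panel <- small_cohort()$panel
  # 4 cells on a line: for N = 3 every cell sees all others
  cells <- data.frame(core_id = "c", patient_id = "p",
                      cell_id = paste0("x", 1:4),
                      x_um = c(0, 1, 2, 3), y_um = 0,
                      cell_type = c("tumor", "tumor", "fibroblast",
                                    "tumor"))
  h <- knn_composition(cells, 3, "tumor", panel)
  expect_equal(h[1, ], c(tumor = 2 / 3, nontumor = 1 / 3))
  expect_equal(h[3, ], c(tumor = 1, nontumor = 0))  # self excluded
  expect_equal(rowSums(h), rep(1, 4))
})

test_that("metabolic histograms allow multi-pathway membership", {
  panel <- small_cohort()$panel
  cells <- data.frame(core_id = "c", patient_id = "p",
                      cell_id = paste0("x", 1:3),
                      x_um = c(0, 1, 2), y_um = 0,
                      cell_type = "tumor")
  for (m in panel$metabolic_markers)
    cells[[paste0(m, "_pos")]] <- FALSE
  # neighbours of cell 1 are cells 2 and 3, each positive for 2 pathways
  cells$GLUT1_pos <- c(FALSE, TRUE, TRUE)
  cells$G6PD_pos <- c(FALSE, TRUE, TRUE)
  h <- knn_composition(cells, 2, "metabolic", panel)
  expect_equal(sum(h[1, ]), 4)  # 2 neighbours x 2 pathways
  expect_equal(unname(h[1, c("Glycolysis", "PPP")]), c(2, 2))
  # all pathway-negative neighbours give a zero vector
  cells2 <- cells
  cells2$GLUT1_pos <- cells2$G6PD_pos <- FALSE
  expect_equal(sum(knn_composition(cells2, 2, "metabolic", panel)[1, ]), 0)
})

test_that("small cores are skipped with a warning, not an error", {
  panel <- small_cohort()$panel
  cells <- data.frame(core_id = c("tiny", "tiny", "tiny"),
                      patient_id = "p", cell_id = paste0("x", 1:3),
                      x_um = 1:3, y_um = 0, cell_type = "tumor")
  expect_warning(h <- knn_composition(cells, 5, "tumor", panel),
                 "unlabelled")
  expect_true(all(is.na(h)))
})

test_that("planted tumor/stroma partition is recovered at K = 2", {
  cfg <- synthetic_config(n_patients = 2, cells_per_core = c(1800, 2000),
                          nest_exclusion = 1, seed = 23)
  co <- generate_cohort(cfg)
  ph <- phenotype_cells(co$cells, cfg$panel)
  h <- knn_composition(ph$cells, 50, "tumor", cfg$panel)
  m <- fit_neighborhoods(h, 2, seed = 5, basis = "tumor")
  acc <- mean((m$labels == "tumor") ==
                (ph$cells$true_region == "nest"), na.rm = TRUE)
  expect_gte(acc, 0.95)
  expect_setequal(m$label_map, c("tumor", "stroma"))
})

test_that("K = 3 adds an interface between tumor and stroma", {
  cfg <- synthetic_config(n_patients = 2, cells_per_core = c(1800, 2000),
                          seed = 29)
  co <- generate_cohort(cfg)
  ph <- phenotype_cells(co$cells, cfg$panel)
  h <- knn_composition(ph$cells, 30, "tumor", cfg$panel)
  m <- fit_neighborhoods(h, 3, seed = 5, basis = "tumor")
  expect_setequal(m$label_map, c("tumor", "interface", "stroma"))
  d <- ph$cells$true_nest_dist
  # interface cells sit between tumor-core and deep-stroma cells
  med <- tapply(d, m$labels, median)
  expect_lt(med[["tumor"]], med[["interface"]])
  expect_lt(med[["interface"]], med[["stroma"]])
})

test_that("planted 4-level metabolic gradient is recovered as MBNs", {
  grad <- list(Glycolysis = c(.85, .05), ATPSynthesis = c(.8, .05),
               TCACycle = c(.75, .05), AminoAcidUptake = c(.7, .05),
               PPP = c(.6, .05), FAOxidation = c(.5, .05),
               OxRegulatory = c(.45, .05))
  cfg <- synthetic_config(n_patients = 2, cells_per_core = c(2500, 2500),
                          n_tumor_nests = 1, nest_radius = 90,
                          metabolic_levels = 4, metabolic_gradient = grad,
                          seed = 31)
  co <- generate_cohort(cfg)
  ph <- phenotype_cells(co$cells, cfg$panel)
  h <- knn_composition(ph$cells, 30, "metabolic", cfg$panel)
  m <- fit_neighborhoods(h, 4, seed = 5, basis = "metabolic")
  expect_setequal(m$label_map,
                  c("minimal", "low", "medium_regulatory", "high"))
  ari <- rand_index_adj(m$labels, ph$cells$true_metabolic_level)
  expect_gte(ari, 0.8)
  # semantic ordering matches planted intensity
  mlev <- tapply(ph$cells$true_metabolic_level, m$labels, mean)
  expect_true(mlev[["minimal"]] < mlev[["low"]])
  expect_true(mlev[["medium_regulatory"]] < mlev[["high"]])
})

test_that("identical histograms raise a degenerate-clustering error", {
  h <- matrix(0.5, nrow = 40, ncol = 2,
              dimnames = list(NULL, c("tumor", "nontumor")))
  expect_error(fit_neighborhoods(h, 2, seed = 1), "degenerate")
})

test_that("assignments are invariant to row permutation and translation", {
  cfg <- synthetic_config(n_patients = 1, cells_per_core = c(600, 600),
                          seed = 37)
  co <- generate_cohort(cfg)
  ph <- phenotype_cells(co$cells, cfg$panel)
  h1 <- knn_composition(ph$cells, 30, "tumor", cfg$panel)
  m1 <- fit_neighborhoods(h1, 2, seed = 9)
  perm <- sample(nrow(ph$cells))
  h2 <- knn_composition(ph$cells[perm, ], 30, "tumor", cfg$panel)
  shifted <- ph$cells
  shifted$x_um <- shifted$x_um + 1234.5
  shifted$y_um <- shifted$y_um - 987.1
  h3 <- knn_composition(shifted, 30, "tumor", cfg$panel)
  expect_equal(h2[order(perm), ], h1)
  expect_equal(h3, h1)
  # refit with the same seed is bitwise stable
  m2 <- fit_neighborhoods(h1, 2, seed = 9)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$centroids, m2$centroids)
})

test_that("elbow analysis finds planted cluster counts and stays monotone", {
  set.seed(51)
  centers <- matrix(rnorm(4 * 7, sd = 6), 4, 7)
  X <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(150 * 7), 150, 7), 2, centers[k, ], "+")))
  colnames(X) <- paste0("f", 1:7)
  el <- elbow_inertia(X, 2:8, seed = 3)
  expect_equal(el$knee, 4)
  expect_true(el$pronounced)
  expect_true(all(diff(el$inertia) <= 1e-8))
  # a single Gaussian blob has no pronounced knee
  blob <- matrix(rnorm(600 * 7), 600, 7)
  el2 <- elbow_inertia(blob, 2:8, seed = 3)
  expect_false(el2$pronounced)
  expect_error(elbow_inertia(X, 1:5, seed = 1), "2, 12")
})

test_that("model serialization writes label map and centroids", {
  co <- small_cohort()
  h <- knn_composition(co$cells, 20, "tumor", co$panel)
  m <- fit_neighborhoods(h, 2, seed = 4)
  base <- tempfile()
  write_nbhd_model(m, base)
  y <- yaml::read_yaml(paste0(base, ".yaml"))
  expect_equal(unlist(y$label_map), m$label_map)
  cen <- read.csv(paste0(base, "_centroids.csv"))
  expect_equal(as.matrix(cen), m$centroids, ignore_attr = TRUE,
               tolerance = 1e-6)
})
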