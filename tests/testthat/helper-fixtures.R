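# Shared fixtures built in code. Small cohorts are cached per test run so
# several test files can reuse the same generated data.

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_patients = 6, cells_per_core = c(700, 900),
                              seed = 11)
      co <- generate_cohort(cfg)
      ph <- phenotype_cells(co$cells, cfg$panel)
      cache <<- list(config = cfg, cells = ph$cells,
                     thresholds = ph$thresholds, clinical = co$clinical,
                     truth = co$truth, panel = cfg$panel)
    }
    cache
  }
})

# independent adjusted Rand index (contingency-table formula)
rand_index_adj <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  tb <- table(a[ok], b[ok])
  n <- sum(tb)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tb))
  sum_a <- sum(comb2(rowSums(tb)))
  sum_b <- sum(comb2(colSums(tb)))
  exp_ <- sum_a * sum_b / comb2(n)
  max_ <- (sum_a + sum_b) / 2
  (sum_ij - exp_) / (max_ - exp_)
}

# brute-force nearest-neighbour distances (oracle for the compiled kernel)
brute_nn_dist <- function(ref, target, self = FALSE) {
  vapply(seq_len(nrow(ref)), function(i) {
    d <- sqrt((target[, 1] - ref[i, 1])^2 + (target[, 2] - ref[i, 2])^2)
    if (self) d[i] <- Inf
    min(d)
  }, numeric(1))
}

# area under the ECDF of nearest-neighbour distances up to r_max,
# written as the average truncated exceedance (closed form of the integral)
brute_gcross_auc <- function(d, r_max = 150) {
  sum(ifelse(d < r_max, r_max - d, 0)) / (length(d) * r_max)
}

random_points <- function(n, lim = 300) {
  cbind(runif(n, 0, lim), runif(n, 0, lim))
}
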