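# empirical fraction of class samples with E_i > E_j, by direct counting
ordering_freq <- function(cohort, gi, gj, class) {
  cols <- names(cohort$labels)[cohort$labels == class]
  mean(cohort$matrix[gi, cols] > cohort$matrix[gj, cols])
}

test_that("the same config and seed yield a bit-identical cohort", {
  cfg <- cohort_config(rng_seed = 42L, missing_rate = 0.02)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth, b$truth)
})

test_that("planted stabilities of 1.0 give empirical frequencies of exactly 1", {
  cfg <- cohort_config(
    n_samples_per_class = c(control = 50, case = 50),
    planted_reversed_pairs = data.frame(gene_i = 1L, gene_j = 2L,
                                        stability_control = 1, stability_case = 1),
    rng_seed = 7L)
  co <- generate_cohort(cfg)
  expect_identical(ordering_freq(co, "g0001", "g0002", "control"), 1)
  expect_identical(1 - ordering_freq(co, "g0001", "g0002", "case"), 1)
})

test_that("planted stability 0.95 at n=100+100 is recovered within 0.05 by counting", {
  co <- generate_cohort(cohort_config(rng_seed = 1L))
  f_ctrl <- ordering_freq(co, "g0001", "g0002", "control")
  f_case <- 1 - ordering_freq(co, "g0001", "g0002", "case")
  expect_lt(abs(f_ctrl - 0.95), 0.05)
  expect_lt(abs(f_case - 0.95), 0.05)
})

test_that("planted frequencies land within 3 binomial SEs of the target", {
  for (seed in 1:5) {
    s_ctrl <- 0.9
    s_case <- 0.85
    co <- generate_cohort(cohort_config(
      n_samples_per_class = c(control = 80, case = 120),
      planted_reversed_pairs = data.frame(gene_i = 3L, gene_j = 9L,
                                          stability_control = s_ctrl,
                                          stability_case = s_case),
      rng_seed = seed))
    tol_ctrl <- 3 * sqrt(s_ctrl * (1 - s_ctrl) / 80)
    tol_case <- 3 * sqrt(s_case * (1 - s_case) / 120)
    expect_lte(abs(ordering_freq(co, "g0003", "g0009", "control") - s_ctrl),
               tol_ctrl)
    expect_lte(abs(1 - ordering_freq(co, "g0003", "g0009", "case") - s_case),
               tol_case)
  }
})

test_that("a signal-free cohort yields an empty signature at threshold 0.85", {
  co <- generate_cohort(cohort_config(planted_reversed_pairs = NULL,
                                      rng_seed = 11L))
  sig <- discover_signature(co$matrix, co$labels)
  expect_identical(nrow(sig$pairs), 0L)
})

test_that("expression is strictly positive before missingness and dims match config", {
  cfg <- cohort_config(n_genes = 60, n_samples_per_class = c(control = 9, case = 13),
                       planted_reversed_pairs = NULL, rng_seed = 2L)
  co <- generate_cohort(cfg)
  expect_identical(dim(co$matrix), c(60L, 22L))
  expect_true(all(co$matrix > 0))

  withmiss <- generate_cohort(cohort_config(missing_rate = 0.1, rng_seed = 5L))
  frac <- mean(is.na(withmiss$matrix))
  expect_lt(abs(frac - 0.1), 0.02)
  expect_true(all(withmiss$matrix > 0, na.rm = TRUE))
})

test_that("identity distortion returns the input and random distortion keeps ranks", {
  co <- generate_cohort(cohort_config(n_genes = 40,
                                      n_samples_per_class = c(control = 5, case = 5),
                                      monotone_distortion = no_distortion(),
                                      rng_seed = 3L))
  expect_identical(apply_monotone_distortion(co$matrix, no_distortion()),
                   co$matrix)

  withr::with_seed(99, {
    distorted <- apply_monotone_distortion(co$matrix)
  })
  expect_false(identical(distorted, co$matrix))
  for (s in seq_len(ncol(co$matrix))) {
    expect_identical(rank(distorted[, s]), rank(co$matrix[, s]))
  }

  neg <- co$matrix
  neg[1, 1] <- -1
  expect_error(apply_monotone_distortion(neg), "strictly positive")
})

test_that("invalid configurations are rejected with diagnostics", {
  expect_error(cohort_config(planted_reversed_pairs = data.frame(
    gene_i = 1L, gene_j = 1L, stability_control = 0.9, stability_case = 0.9)),
    "distinct")
  expect_error(cohort_config(planted_reversed_pairs = data.frame(
    gene_i = 1L, gene_j = 500L, stability_control = 0.9, stability_case = 0.9)),
    "outside")
  expect_error(cohort_config(planted_reversed_pairs = data.frame(
    gene_i = 1L, gene_j = 2L, stability_control = 1.2, stability_case = 0.9)),
    "stabilities")
  # planted structure demanding more genes than exist (pair genes may not
  # double as DE genes, which could contradict the planted direction)
  expect_error(cohort_config(n_genes = 10, n_de_genes = 9), "distinct genes")
})

test_that("config YAML round-trips through read/write", {
  cfg <- cohort_config(n_genes = 50, n_de_genes = 5, rng_seed = 17L,
                       missing_rate = 0.05)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, path)
  back <- read_cohort_config(path)
  expect_equal(back$n_genes, cfg$n_genes)
  expect_equal(back$monotone_distortion, cfg$monotone_distortion)
  expect_equal(back$planted_reversed_pairs, cfg$planted_reversed_pairs)
  expect_identical(generate_cohort(back)$matrix, generate_cohort(cfg)$matrix)
})

test_that("cohorts write to disk and read back consistently", {
  co <- generate_cohort(cohort_config(n_genes = 20,
                                      n_samples_per_class = c(control = 4, case = 4),
                                      rng_seed = 9L))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  mat <- read_matrix(file.path(dir, "matrix.tsv"))
  labels <- read_labels(file.path(dir, "labels.tsv"))
  expect_equal(mat, co$matrix)
  expect_identical(labels, co$labels)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(truth$pairs$gene_i, co$truth$gene_i)
})
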