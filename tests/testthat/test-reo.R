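test_that("the ordering oracle answers gt/lt/tie/missing and rejects unknown genes", {
  mat <- make_matrix(c(5, 3, NA, 2, 2, 1), 3, 2)
  enc <- encode_reo(mat)
  expect_identical(reo_state(enc, "g1", "g2", "s1"), "i_gt_j")
  expect_identical(reo_state(enc, "g2", "g1", "s1"), "i_lt_j")
  expect_identical(reo_state(enc, "g1", "g2", "s2"), "tie")
  expect_identical(reo_state(enc, "g1", "g3", "s1"), "missing")
  expect_error(reo_state(enc, "g1", "nope", "s1"), "unknown gene")
  expect_error(encode_reo(mat, genes = c("g1", "nope")), "unknown gene")
})

test_that("orderings are invariant under strictly increasing per-sample transforms", {
  mat <- make_matrix(stats::runif(40, 1, 100), 8, 5)
  warped <- apply(mat, 2L, function(x) log(x) * 3 + 7)
  dimnames(warped) <- dimnames(mat)
  enc_a <- encode_reo(mat)
  enc_b <- encode_reo(warped)
  for (s in colnames(mat)) {
    for (i in 1:7) for (j in (i + 1):8) {
      gi <- paste0("g", i); gj <- paste0("g", j)
      expect_identical(reo_state(enc_a, gi, gj, s), reo_state(enc_b, gi, gj, s))
    }
  }
})

test_that("hand-constructed 3-gene case reports only the pair above threshold", {
  # g1 > g2 in 4/4 samples, g1 > g3 in 3/4, g2 > g3 in 2/4
  mat <- make_matrix(c(
    9, 5, 1,   # s1: g1>g2>g3
    9, 5, 6,   # s2: g1>g3>g2
    9, 5, 2,   # s3: g1>g2>g3
    4, 3, 8),  # s4: g3>g1>g2
    3, 4)
  sp <- mine_stable_pairs(mat, threshold = 0.85, min_evaluable = 1)
  expect_identical(nrow(sp), 1L)
  expect_identical(sp$gene_i, "g1")
  expect_identical(sp$gene_j, "g2")
  expect_identical(sp$direction, "i_gt_j")
  expect_identical(sp$frequency, 1)
  expect_identical(sp$support, 4L)
  expect_identical(sp$evaluable, 4L)

  # at threshold 1.0 the perfectly ordered pair is still the only survivor
  sp1 <- mine_stable_pairs(mat, threshold = 1, min_evaluable = 1)
  expect_identical(nrow(sp1), 1L)

  expect_error(mine_stable_pairs(mat, threshold = 0.5), "threshold")
  expect_error(mine_stable_pairs(mat, threshold = 0.4), "threshold")
})

test_that("ties stay in the denominator and erode stability", {
  # g1 vs g2: greater in 3 samples, tied in 1 -> frequency 0.75, not 1
  mat <- make_matrix(c(5, 1, 5, 2, 5, 3, 4, 4), 2, 4)
  sp <- mine_stable_pairs(mat, threshold = 0.7, min_evaluable = 1)
  expect_identical(sp$frequency, 0.75)
  expect_identical(sp$evaluable, 4L)
  expect_identical(nrow(mine_stable_pairs(mat, threshold = 0.8,
                                          min_evaluable = 1)), 0L)
})

test_that("missing values leave the denominator and min_evaluable guards sparse pairs", {
  mat <- make_matrix(c(5, 1, NA, 2, 6, 3, 7, NA), 2, 4)
  # evaluable samples: s1 (5>1) and s3 (6>3) -> frequency 1 over 2
  sp <- mine_stable_pairs(mat, threshold = 0.85, min_evaluable = 2)
  expect_identical(sp$evaluable, 2L)
  expect_identical(sp$frequency, 1)
  expect_identical(nrow(mine_stable_pairs(mat, threshold = 0.85,
                                          min_evaluable = 3)), 0L)
})

test_that("mining matches the brute-force oracle on random small matrices", {
  withr::with_seed(123, {
    for (rep in 1:30) {
      mat <- random_reo_matrix(sample(3:12, 1), sample(4:10, 1))
      thr <- sample(c(0.6, 0.75, 0.85, 1), 1)
      sp <- mine_stable_pairs(mat, threshold = thr, min_evaluable = 1)
      expect_same_pairs(sp, oracle_stable_pairs(mat, thr, 1))
    }
  })
})

test_that("mining is invariant under monotone distortion and symmetric in classes", {
  co <- generate_cohort(cohort_config(n_genes = 30, rng_seed = 21L))
  ctrl <- names(co$labels)[co$labels == "control"]
  case <- names(co$labels)[co$labels == "case"]
  withr::with_seed(5, distorted <- apply_monotone_distortion(co$matrix))
  expect_same_pairs(mine_stable_pairs(co$matrix, ctrl),
                    mine_stable_pairs(distorted, ctrl))
  expect_same_pairs(mine_stable_pairs(co$matrix, case),
                    mine_stable_pairs(distorted, case))

  # swapping class roles maps reversed pairs onto themselves
  sc <- mine_stable_pairs(co$matrix, ctrl, class_label = "control")
  sa <- mine_stable_pairs(co$matrix, case, class_label = "case")
  fwd <- find_reversed_pairs(sc, sa)
  bwd <- find_reversed_pairs(sa, sc)
  expect_identical(fwd$reversed$gene_i, bwd$reversed$gene_i)
  expect_identical(fwd$reversed$gene_j, bwd$reversed$gene_j)
  expect_identical(fwd$reversed$direction_control, bwd$reversed$direction_case)
})

test_that("reversal intersection separates opposite- and same-direction overlap", {
  mk <- function(df, label, thr = 0.85, n = 10) {
    structure(df, class = c("stable_pair_set", "data.frame"),
              class_label = label, threshold = thr, n_samples = n,
              min_evaluable = 5)
  }
  ctrl <- mk(data.frame(gene_i = c("a", "c"), gene_j = c("b", "d"),
                        direction = c("i_gt_j", "i_gt_j"),
                        support = c(9, 9), evaluable = c(10, 10),
                        frequency = c(0.9, 0.9), stringsAsFactors = FALSE),
             "control")
  case <- mk(data.frame(gene_i = c("a", "c"), gene_j = c("b", "d"),
                        direction = c("i_lt_j", "i_gt_j"),
                        support = c(10, 10), evaluable = c(10, 10),
                        frequency = c(1, 1), stringsAsFactors = FALSE),
             "case")
  res <- find_reversed_pairs(ctrl, case)
  expect_identical(res$reversed$gene_i, "a")
  expect_identical(res$same_direction$gene_i, "c")
  expect_identical(res$reversed$frequency_control, 0.9)
  expect_identical(res$reversed$frequency_case, 1)

  case_mismatch <- mk(as.data.frame(case), "case", thr = 0.9)
  expect_warning(res2 <- find_reversed_pairs(ctrl, case_mismatch),
                 "threshold mismatch")
  expect_identical(res2$provenance$warning,
                   "threshold mismatch: control 0.85 vs case 0.9")
})

test_that("stable-pair sets serialize to TSV with class and threshold columns", {
  mat <- make_matrix(c(9, 5, 1, 8, 4, 2), 3, 2)
  sp <- mine_stable_pairs(mat, threshold = 0.85, min_evaluable = 1,
                          class_label = "control")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stable_pairs(sp, path)
  back <- utils::read.delim(path)
  expect_identical(nrow(back), nrow(sp))
  expect_true(all(back$class == "control"))
  expect_true(all(back$threshold == 0.85))
})
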