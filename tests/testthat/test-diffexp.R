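test_that("BH adjustment matches the step-up definition", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  withr::with_seed(2, {
    for (rep in 1:20) {
      p <- stats::runif(sample(2:6, 1))
      expect_equal(stats::p.adjust(p, method = "BH"), oracle_bh(p))
    }
  })
})

test_that("planted DE genes are recovered with correct directions", {
  cfg <- cohort_config(n_genes = 300, planted_reversed_pairs = NULL,
                       n_de_genes = 50, de_log_fold_change = 2,
                       n_samples_per_class = c(control = 40, case = 40),
                       rng_seed = 30L)
  co <- generate_cohort(cfg)
  deg <- wilcoxon_deg(co$matrix, co$labels)
  hits <- deg[deg$significant, ]
  expect_true(all(co$truth_de$gene %in% hits$gene))
  found <- merge(hits, co$truth_de, by = "gene")
  expect_true(all(found$direction ==
                    ifelse(found$sign > 0, "up_in_case", "down_in_case")))
  # fdr never dips below p after step-up monotonicity
  expect_true(all(deg$fdr >= deg$p_value - 1e-12))
})

test_that("constant genes are kept with p = 1 and no direction", {
  mat <- make_matrix(c(1, 5, 1, 6, 1, 4, 1, 7), 2, 4)
  labels <- stats::setNames(rep(c("case", "control"), each = 2),
                            colnames(mat))
  deg <- wilcoxon_deg(mat, labels)
  expect_identical(deg$p_value[deg$gene == "g1"], 1)
  expect_identical(deg$direction[deg$gene == "g1"], "none")
  expect_error(wilcoxon_deg(mat[, 1:2], labels[1:2]), "at least 2 samples")
})

test_that("a null cohort produces almost no significant genes", {
  co <- generate_cohort(cohort_config(n_genes = 500,
                                      planted_reversed_pairs = NULL,
                                      n_samples_per_class = c(control = 30, case = 30),
                                      rng_seed = 40L))
  deg <- wilcoxon_deg(co$matrix, co$labels)
  expect_lt(mean(deg$significant), 0.005)
})

test_that("consistent DEGs require significance and matching signs in both cohorts", {
  mk <- function(genes, dirs, fdrs, sig) {
    structure(data.frame(gene = genes, statistic = 1, p_value = fdrs,
                         fdr = fdrs, direction = dirs, median_case = 1,
                         median_control = 1, significant = sig,
                         stringsAsFactors = FALSE),
              class = c("deg_table", "data.frame"), fdr_cutoff = 0.01,
              case_label = "case", control_label = "control")
  }
  a <- mk(c("g1", "g2", "g3", "g4"),
          c("up_in_case", "up_in_case", "down_in_case", "none"),
          c(0.001, 0.001, 0.001, 0.001), c(TRUE, TRUE, TRUE, TRUE))
  b <- mk(c("g1", "g2", "g3", "g4"),
          c("up_in_case", "down_in_case", "down_in_case", "up_in_case"),
          c(0.001, 0.001, 0.2, 0.001), c(TRUE, TRUE, FALSE, TRUE))
  cons <- consistent_degs(a, b)
  expect_identical(cons$gene, "g1")   # g2 flips, g3 not significant in b, g4 signless
  expect_identical(cons$direction, "up_in_case")
})

test_that("shared planted DE genes across two cohorts are exactly the consistent set", {
  base <- cohort_config(n_genes = 200, planted_reversed_pairs = NULL,
                        n_de_genes = 30, de_log_fold_change = 2.5,
                        n_samples_per_class = c(control = 40, case = 40),
                        rng_seed = 50L)
  co_a <- generate_cohort(base)
  base$rng_seed <- 51L
  co_b <- generate_cohort(base)
  # identical configs plant the same DE genes with the same signs
  expect_identical(co_a$truth_de, co_b$truth_de)
  cons <- consistent_degs(wilcoxon_deg(co_a$matrix, co_a$labels),
                          wilcoxon_deg(co_b$matrix, co_b$labels))
  expect_setequal(cons$gene, co_a$truth_de$gene)
})

test_that("a duplicated seed yields a perfect edge and self-pairs are skipped", {
  withr::with_seed(61, mat <- make_matrix(stats::runif(500, 1, 10), 5, 100))
  mat <- rbind(mat, copy = mat["g1", ] + 0.001)
  net <- coexpression_network(mat, "g1", rownames(mat),
                              rank_within_sample = FALSE)
  expect_true("copy" %in% net$partner_gene)
  expect_equal(net$rho[net$partner_gene == "copy"], 1)
  expect_identical(net$sign[net$partner_gene == "copy"], "positive")
  expect_false(any(net$partner_gene == "g1"))
  tested <- attr(net, "tested")
  expect_identical(nrow(tested), 5L)   # 6 candidates minus the seed itself
  expect_error(coexpression_network(mat[, 1:3], "g1", "g2"), "4 samples")
})

test_that("independent noise produces no edges but planted modules are recovered", {
  co <- generate_cohort(cohort_config(n_genes = 120,
                                      planted_reversed_pairs = NULL,
                                      n_correlated_modules = 1,
                                      module_size = 10,
                                      module_correlation = 0.8,
                                      n_samples_per_class = c(control = 50, case = 50),
                                      rng_seed = 70L))
  module_genes <- co$truth_modules$gene
  noise_genes <- setdiff(rownames(co$matrix), module_genes)
  seed <- module_genes[1]

  net <- coexpression_network(co$matrix, seed, rownames(co$matrix))
  recovered <- intersect(net$partner_gene, module_genes[-1])
  expect_gte(length(recovered), 8L)
  expect_identical(setdiff(net$partner_gene, module_genes), character(0))

  null_net <- coexpression_network(co$matrix, noise_genes[1], noise_genes[-1])
  expect_identical(nrow(null_net), 0L)

  # relaxing the FDR filter can only add edges
  loose <- coexpression_network(co$matrix, seed, rownames(co$matrix),
                                fdr_cutoff = 1)
  key <- function(df) paste(df$seed_gene, df$partner_gene)
  expect_true(all(key(net) %in% key(loose)))
})

test_that("Spearman rho equals Pearson on ranks and matches cor.test", {
  withr::with_seed(81, {
    x <- stats::rnorm(30)
    y <- x + stats::rnorm(30)
  })
  mat <- rbind(a = x, b = y)
  colnames(mat) <- paste0("s", 1:30)
  net <- coexpression_network(mat, "a", "b", rho_cutoff = 0, fdr_cutoff = 1,
                              rank_within_sample = FALSE)
  expect_equal(net$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(net$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(net$p_value, ct$p.value, tolerance = 1e-8)
})

test_that("hypergeometric enrichment has closed-form tails and sane errors", {
  universe <- paste0("g", 1:10)
  sets <- list(hit = paste0("g", 1:5), dud = paste0("g", 6:10))
  res <- hypergeom_enrich(paste0("g", 1:5), sets, universe)
  expect_equal(res$p_value[res$set_name == "hit"], 1 / choose(10, 5))
  expect_equal(res$p_value[res$set_name == "dud"], 1)  # P(X >= 0) = 1
  expect_identical(res$overlap_count[res$set_name == "hit"], 5L)

  expect_error(hypergeom_enrich(c("g1", "zz"), sets, universe),
               "outside the universe")
  expect_warning(hypergeom_enrich("g1", c(sets, list(ghost = "qq")), universe),
                 "ghost")
})

test_that("inflammation tagging emits one row per matching category", {
  sets <- list(chemokine = c("g1", "g2"), cytokine = c("g2", "g3"))
  deg <- data.frame(gene = c("g1", "g2", "g9"),
                    direction = c("up_in_case", "down_in_case", "up_in_case"),
                    stringsAsFactors = FALSE)
  tagged <- localize_inflammation_genes(deg, sets)
  expect_identical(sum(tagged$gene == "g2"), 2L)
  expect_setequal(tagged$category[tagged$gene == "g2"],
                  c("chemokine", "cytokine"))
  expect_identical(tagged$category[tagged$gene == "g9"], NA_character_)
  expect_identical(tagged$direction[tagged$gene == "g9"], "up_in_case")
})
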