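# The synthetic cohort generator: determinism, planted-parameter recovery
# through the pipeline stages, and exact QC-defect accounting.

binom_ci_halfwidth <- function(p, n, z = 2.58) z * sqrt(p * (1 - p) / n)

test_that("a fixed config reproduces the cohort exactly", {
  cfg <- simulation_config(seed = 2, cells_per_sample = 80,
                           arms = c(placebo = 1L, IL2_2.5 = 1L))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$chains, s2$chains)
  expect_identical(s1$meta, s2$meta)
  expect_identical(s1$truth$cells, s2$truth$cells)
  # config validation
  expect_error(simulation_config(treg_pre = 1.5), "probabilities")
  expect_error(simulation_config(defect_rates = c(multi_chain = 0.5,
                                                  orphan = 0.5,
                                                  nonproductive = 0.1)),
               "no clean cells")
})

test_that("QC-defect fractions match the planted rates and the truth exactly", {
  # 2% multi-chain, 5% orphan (seed 1, 5000 cells)
  st <- simulate_study(simulation_config(
    seed = 1, cells_per_sample = 2500, arms = c(placebo = 1L),
    defect_rates = c(multi_chain = 0.02, orphan = 0.05, nonproductive = 0.03)))
  res <- qc_single_paired(st$chains, st$meta)
  rep <- res$report
  n <- rep$n_input_cells
  expect_equal(n, 5000)
  # exact agreement with the generator's ground truth
  tc <- st$truth$cells
  expect_equal(rep$n_multi_chain, sum(tc$defect == "multi_chain"))
  expect_equal(rep$n_orphan, sum(tc$defect == "orphan"))
  expect_equal(rep$n_nonproductive_only, sum(tc$defect == "nonproductive"))
  expect_equal(rep$n_invariant_removed,
               sum(tc$defect == "clean" & tc$invariant))
  expect_equal(rep$n_single_paired, sum(tc$defect == "clean" & !tc$invariant))
  # planted rates within the binomial 99% CI
  expect_lt(abs(rep$n_multi_chain / n - 0.02), binom_ci_halfwidth(0.02, n))
  expect_lt(abs(rep$n_orphan / n - 0.05), binom_ci_halfwidth(0.05, n))
  # kept cells carry exactly one alpha and one beta CDR3
  expect_true(all(nchar(res$cells$alpha_cdr3) > 0))
  expect_true(all(startsWith(res$cells$alpha_cdr3, "C")))
})

test_that("post-treatment Treg proportions recover the planted dose response", {
  st <- simulate_study(simulation_config(seed = 11, cells_per_sample = 600))
  qc <- qc_single_paired(st$chains, st$meta)
  planted <- c(placebo = 0.04, IL2_1.5 = 0.06, IL2_2.5 = 0.09)
  for (arm in names(planted)) {
    post <- qc$cells[qc$cells$arm == arm & qc$cells$timepoint == "post", ]
    obs <- mean(post$phenotype == "Treg")
    # CI widened for clonotype-induced overdispersion (cells share a
    # clonotype-level base phenotype)
    hw <- 2 * binom_ci_halfwidth(planted[[arm]], nrow(post))
    expect_lt(abs(obs - planted[[arm]]), hw)
  }
  # pre-treatment fraction is arm-independent at 2%
  pre <- qc$cells[qc$cells$timepoint == "pre", ]
  expect_lt(abs(mean(pre$phenotype == "Treg") - 0.02),
            2 * binom_ci_halfwidth(0.02, nrow(pre)))
})

test_that("planted persistence drives the observed shared-cell fraction", {
  st <- simulate_study(simulation_config(
    seed = 19, cells_per_sample = 1500, arms = c(placebo = 2L, IL2_1.5 = 2L),
    persistence = c(placebo = 0.015, IL2_1.5 = 0.071, IL2_2.5 = 0.035),
    defect_rates = c(multi_chain = 0, orphan = 0, nonproductive = 0),
    invariant_rate = 0))
  qc <- qc_single_paired(st$chains, st$meta)
  sh <- match_clonotypes(define_clonotype_clusters(qc$cells))
  for (arm in c("placebo", "IL2_1.5")) {
    q <- st$truth$persistence[[arm]]
    row <- sh$by_arm[sh$by_arm$arm == arm, ]
    hw <- 2 * binom_ci_halfwidth(q, row$total_cells)
    expect_lt(abs(row$shared_cell_fraction - q), hw)
  }
})

test_that("IL-2 arms lose diversity relative to placebo after treatment", {
  lower <- vapply(1:8, function(s) {
    st <- simulate_study(simulation_config(
      seed = 100 + s, cells_per_sample = 300,
      arms = c(placebo = 2L, IL2_2.5 = 2L),
      defect_rates = c(multi_chain = 0, orphan = 0, nonproductive = 0),
      invariant_rate = 0))
    qc <- qc_single_paired(st$chains, st$meta)
    asn <- define_clonotype_clusters(qc$cells)
    post <- asn$cells[asn$cells$timepoint == "post", ]
    h <- vapply(c("placebo", "IL2_2.5"), function(a) {
      sizes <- as.integer(table(post$clonotype_id[post$arm == a]))
      shannon_entropy(sizes)$shannon_normalized
    }, numeric(1))
    h[["IL2_2.5"]] < h[["placebo"]]
  }, logical(1))
  expect_gte(mean(lower), 0.95)
})

test_that("planted DE genes are recovered through the expression stage", {
  st <- simulate_study(simulation_config(
    seed = 29, cells_per_sample = 1200, arms = c(IL2_2.5 = 2L),
    treg_post = c(placebo = 0.04, IL2_1.5 = 0.06, IL2_2.5 = 0.25),
    clone_size_p_post = c(placebo = 0.7, IL2_1.5 = 0.6, IL2_2.5 = 0.45),
    defect_rates = c(multi_chain = 0, orphan = 0, nonproductive = 0),
    invariant_rate = 0,
    expression = list(n_genes = 400, n_de = 10, de_log2fc = 1, nb_size = 2,
                      base_mean_meanlog = log(0.5), base_mean_sdlog = 0.6)))
  sim <- simulate_expression(st)
  expect_gte(sum(sim$labels), 40)
  de <- differential_expression(sim$expr, sim$labels)
  found <- de[match(sim$de_genes$gene, de$gene), ]
  expect_gte(mean(found$significant, na.rm = TRUE), 0.8)
  expect_lt(median(abs(found$log2fc - 1), na.rm = TRUE), 0.2)
  # determinism of the expression draw
  sim2 <- simulate_expression(st)
  expect_identical(sim$expr, sim2$expr)
})

test_that("pipeline-derived expansion labels agree with the generator truth", {
  st <- simulate_study(simulation_config(
    seed = 37, cells_per_sample = 800, arms = c(IL2_2.5 = 2L),
    treg_post = c(placebo = 0.04, IL2_1.5 = 0.06, IL2_2.5 = 0.2),
    clone_size_p_post = c(placebo = 0.7, IL2_1.5 = 0.6, IL2_2.5 = 0.5),
    defect_rates = c(multi_chain = 0, orphan = 0, nonproductive = 0),
    invariant_rate = 0))
  qc <- qc_single_paired(st$chains, st$meta)
  asn <- define_clonotype_clusters(qc$cells)
  lab <- label_expanded(asn)
  truth_lab <- st$truth$cells$expanded_treg[match(lab$cell_id,
                                                  st$truth$cells$cell_id)]
  expect_gt(mean(lab$expanded == truth_lab), 0.99)
})

test_that("reference CDR3 sets carry well-formed labels and planted motifs", {
  sets <- emit_reference_cdr3_sets(seed = 5)
  expect_setequal(unique(sets$reference$dataset_label),
                  c("athero_ref", "HC_ref"))
  expect_true(all(grepl("^C[ACDEFGHIKLMNPQRSTVWY]+[FW]$", sets$query$cdr3_aa)))
  # planted motifs really occur in the trimmed interiors
  fam <- sets$truth
  ok <- mapply(function(s, m) grepl(m, trim_cdr3(s), fixed = TRUE),
               fam$cdr3_aa, fam$family)
  expect_true(all(ok))
  # ground-truth JSON writer round-trips without the config blob
  st <- simulate_study(simulation_config(seed = 3, cells_per_sample = 50,
                                         arms = c(placebo = 1L)))
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(st$truth, f)
  j <- jsonlite::read_json(f)
  expect_true(all(c("cells", "clones", "kernels", "persistence") %in% names(j)))
})
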