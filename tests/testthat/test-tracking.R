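# Longitudinal clonotype matching, transition tables/tests and empirical
# transition matrices.

# helper: tracked-cells tibble -> shared_clonotypes via make_assignment
tracked_fixture <- function(df) {
  df$cell_id <- sprintf("c%03d", seq_len(nrow(df)))
  df$alpha_cdr3 <- "CAVSDGKLTF"; df$beta_cdr3 <- "CASSLGETQYF"
  match_clonotypes(make_assignment(df))
}

test_that("clonotype sharing requires both timepoints within a patient", {
  df <- tibble::tibble(
    clonotype_id = c("ct1", "ct1", "ct2", "ct3", "ct3", "ct3", "ct3", "ct3"),
    patient_id = "placebo_pt01", arm = "placebo",
    timepoint = c("pre", "post", "pre", "pre", "pre", "post", "post", "post"),
    phenotype = "CD4_Tem")
  sh <- tracked_fixture(df)
  expect_equal(sh$by_arm$n_shared_clonotypes, 2) # ct1 and ct3
  expect_equal(sh$by_arm$n_shared_cells, 7)      # ct1: 2, ct3: 5
  expect_equal(sh$by_arm$total_cells, 8)
  expect_false(any(sh$cells$shared[sh$cells$clonotype_id == "ct2"]))
})

test_that("patients missing a timepoint are excluded with a warning", {
  df <- tibble::tibble(
    clonotype_id = c("ct1", "ct1", "ct9"),
    patient_id = c("placebo_pt01", "placebo_pt01", "placebo_pt02"),
    arm = "placebo",
    timepoint = c("pre", "post", "pre"),
    phenotype = "Treg")
  df$cell_id <- sprintf("c%03d", seq_len(nrow(df)))
  expect_warning(sh <- match_clonotypes(make_assignment(df)), "pt02")
  expect_false("placebo_pt02" %in% sh$by_patient$patient_id)
})

test_that("sharing is symmetric in timepoints and tables transpose", {
  df <- tibble::tibble(
    clonotype_id = rep(c("ct1", "ct2"), c(4, 3)),
    patient_id = "placebo_pt01", arm = "placebo",
    timepoint = c("pre", "pre", "post", "post", "pre", "post", "post"),
    phenotype = c("Treg", "CD4_Tcm", "CD4_Tem", "Treg",
                  "Treg", "CD4_Tcm", "CD4_Tem"))
  sh <- tracked_fixture(df)
  tab <- build_transition_table(sh, "placebo")
  flipped <- df
  flipped$timepoint <- ifelse(df$timepoint == "pre", "post", "pre")
  tab2 <- build_transition_table(tracked_fixture(flipped), "placebo")
  expect_equal(unclass(tab)["pre", ], unclass(tab2)["post", ])
  expect_equal(unclass(tab)["post", ], unclass(tab2)["pre", ])
})

test_that("shared-fraction chi-squared matches the direct Pearson computation", {
  df <- tibble::tibble(
    clonotype_id = c(rep("ct1", 4), rep("ct2", 4)),
    patient_id = rep(c("placebo_pt01", "IL2_1.5_pt01"), each = 4),
    arm = rep(c("placebo", "IL2_1.5"), each = 4),
    timepoint = rep(c("pre", "post", "pre", "pre"), 2),
    phenotype = "Treg")
  # make arm fractions differ: drop sharing in placebo
  df$clonotype_id[3:4] <- c("ct8", "ct9")
  sh <- tracked_fixture(df)
  res <- shared_fraction_test(sh)
  m <- rbind(c(sh$by_arm$n_shared_cells[sh$by_arm$arm == "placebo"],
               sh$by_arm$total_cells[sh$by_arm$arm == "placebo"] -
                 sh$by_arm$n_shared_cells[sh$by_arm$arm == "placebo"]),
             c(sh$by_arm$n_shared_cells[sh$by_arm$arm == "IL2_1.5"],
               sh$by_arm$total_cells[sh$by_arm$arm == "IL2_1.5"] -
                 sh$by_arm$n_shared_cells[sh$by_arm$arm == "IL2_1.5"]))
  expect_equal(res[["IL2_1.5"]]$statistic, chi2_independence(m)$statistic)
  # trial-scale counts against the brute-force Pearson formula
  big <- rbind(c(76, 5000 - 76), c(544, 7700 - 544))
  e <- outer(rowSums(big), colSums(big)) / sum(big)
  expect_equal(chi2_independence(big)$statistic, sum((big - e)^2 / e),
               tolerance = 1e-12)
})

test_that("transition tables reproduce the published tracked counts", {
  # placebo, Treg-touching clonotypes: 6 Treg + 1 Tcm -> 1 Treg + 3 Tcm + 2 Tem
  df <- tibble::tibble(
    clonotype_id = "ct1", patient_id = "placebo_pt01", arm = "placebo",
    timepoint = rep(c("pre", "post"), c(7, 6)),
    phenotype = c(rep("Treg", 6), "CD4_Tcm",
                  "Treg", rep("CD4_Tcm", 3), rep("CD4_Tem", 2)))
  sh <- tracked_fixture(df)
  tab <- build_transition_table(sh, "placebo", restrict_to = "Treg")
  expect_equal(unclass(tab)[, c("Treg", "Tcm", "Tem")],
               matrix(c(6, 1, 1, 3, 0, 2), 2,
                      dimnames = list(c("pre", "post"), c("Treg", "Tcm", "Tem"))))
  expect_equal(signif(transition_significance(tab), 3), 0.0414)
  # 2.5 MIU: (4 Treg, 3 Tcm, 1 Tem) -> (6 Treg, 4 Tcm, 1 Tem)
  df2 <- tibble::tibble(
    clonotype_id = "ct1", patient_id = "IL2_2.5_pt01", arm = "IL2_2.5",
    timepoint = rep(c("pre", "post"), c(8, 11)),
    phenotype = c(rep("Treg", 4), rep("CD4_Tcm", 3), "CD4_Tem",
                  rep("Treg", 6), rep("CD4_Tcm", 4), "CD4_Tem"))
  tab2 <- build_transition_table(tracked_fixture(df2), "IL2_2.5",
                                 restrict_to = "Treg")
  expect_equal(unname(unclass(tab2)[, c("Treg", "Tcm", "Tem")]),
               rbind(c(4, 3, 1), c(6, 4, 1)))
})

test_that("transition significance drops empty columns and handles degeneracy", {
  tab <- contingency_table(rbind(c(3, 0), c(3, 0)), c("pre", "post"))
  expect_equal(transition_significance(tab), 1)
  tab2 <- contingency_table(rbind(c(5, 0), c(0, 5)))
  expect_equal(transition_significance(tab2),
               fisher.test(rbind(c(5, 0), c(0, 5)))$p.value, tolerance = 1e-9)
  df <- tibble::tibble(clonotype_id = "ct1", patient_id = "placebo_pt01",
                       arm = "placebo", timepoint = c("pre", "post"),
                       phenotype = "CD8_Tem")
  sh <- tracked_fixture(df)
  empty <- build_transition_table(sh, "placebo")
  expect_true(isTRUE(attr(empty, "empty")))
  expect_error(transition_significance(empty), "empty")
})

test_that("empirical transition matrix weights pairs per clonotype", {
  df <- tibble::tibble(clonotype_id = "ct1", patient_id = "placebo_pt01",
                       arm = "placebo", timepoint = c("pre", "post"),
                       phenotype = c("Treg", "CD4_Tem"))
  tm <- empirical_transition_matrix(tracked_fixture(df), "placebo")
  expect_equal(tm$matrix["Treg", "Tem"], 1)
  expect_equal(tm$outgoing[["Treg"]], 1)
  expect_true("Tcm" %in% tm$undefined_rows)
  df2 <- tibble::tibble(clonotype_id = "ct1", patient_id = "placebo_pt01",
                        arm = "placebo", timepoint = c("pre", "post", "post"),
                        phenotype = c("Treg", "Treg", "CD4_Tem"))
  tm2 <- empirical_transition_matrix(tracked_fixture(df2), "placebo")
  expect_equal(unname(tm2$matrix["Treg", c("Treg", "Tem")]), c(0.5, 0.5))
  expect_equal(sum(tm2$weights), 1) # one clonotype totals weight 1
})

test_that("per-clonotype weighting is invariant to duplicating a clonotype's cells", {
  df <- tibble::tibble(
    clonotype_id = rep(c("ct1", "ct2"), c(3, 2)),
    patient_id = "placebo_pt01", arm = "placebo",
    timepoint = c("pre", "post", "post", "pre", "post"),
    phenotype = c("Treg", "Treg", "CD4_Tem", "CD4_Tcm", "CD4_Tcm"))
  m1 <- empirical_transition_matrix(tracked_fixture(df), "placebo")$matrix
  dup <- dplyr::bind_rows(df, df[df$clonotype_id == "ct1", ])
  m2 <- empirical_transition_matrix(tracked_fixture(dup), "placebo")$matrix
  expect_equal(m1, m2)
})

test_that("per-pair and per-clonotype weightings differ when clone sizes differ", {
  # two Treg-source clonotypes of unequal post size: per-clonotype averages
  # their rows (0.5/0.5), per-pair weights the larger clone more (1/3 vs 2/3)
  df <- tibble::tibble(
    clonotype_id = rep(c("ct1", "ct2"), c(2, 3)),
    patient_id = "placebo_pt01", arm = "placebo",
    timepoint = c("pre", "post", "pre", "post", "post"),
    phenotype = c("Treg", "Treg", "Treg", "CD4_Tem", "CD4_Tem"))
  mc <- empirical_transition_matrix(tracked_fixture(df), "placebo")$matrix
  mp <- empirical_transition_matrix(tracked_fixture(df), "placebo",
                                    weighting = "per-pair")$matrix
  expect_equal(unname(mc["Treg", c("Treg", "Tem")]), c(0.5, 0.5))
  expect_equal(unname(mp["Treg", c("Treg", "Tem")]), c(1 / 3, 2 / 3))
})

test_that("transition-matrix rows are stochastic and sankey links conserve flow", {
  st <- simulate_study(simulation_config(
    seed = 31, cells_per_sample = 300, arms = c(IL2_2.5 = 2L),
    persistence = c(placebo = 0.015, IL2_1.5 = 0.071, IL2_2.5 = 0.3),
    defect_rates = c(multi_chain = 0, orphan = 0, nonproductive = 0),
    invariant_rate = 0))
  qc <- qc_single_paired(st$chains, st$meta)
  sh <- match_clonotypes(define_clonotype_clusters(qc$cells))
  tm <- empirical_transition_matrix(sh, "IL2_2.5")
  rs <- rowSums(tm$matrix)
  defined <- !rownames(tm$matrix) %in% tm$undefined_rows
  expect_equal(unname(rs[defined]), rep(1, sum(defined)), tolerance = 1e-9)
  links <- export_sankey(sh, "IL2_2.5")
  expect_equal(sum(links$weight), sum(tm$weights), tolerance = 1e-12)
})

test_that("planted transition kernels are recovered from tracked clonotypes", {
  # stage-isolation config: persistence 0.5 plants thousands of tracked
  # clonotypes, and a balanced Treg base (25%) populates every source row
  st <- simulate_study(simulation_config(
    seed = 47, cells_per_sample = 3000, arms = c(placebo = 3L),
    treg_pre = 0.25, treg_post = c(placebo = 0.25, IL2_1.5 = 0.25, IL2_2.5 = 0.3),
    persistence = c(placebo = 0.5, IL2_1.5 = 0.5, IL2_2.5 = 0.5),
    defect_rates = c(multi_chain = 0, orphan = 0, nonproductive = 0),
    invariant_rate = 0))
  qc <- qc_single_paired(st$chains, st$meta)
  sh <- match_clonotypes(define_clonotype_clusters(qc$cells))
  expect_gte(sh$by_arm$n_shared_clonotypes, 500)
  tm <- empirical_transition_matrix(sh, "placebo")
  truth <- st$truth$kernel_effective$placebo
  err <- max(abs(tm$matrix - truth[rownames(tm$matrix), colnames(tm$matrix)]),
             na.rm = TRUE)
  expect_lt(err, 0.05)
})

test_that("placebo polarizes away from Treg while IL-2 retains it", {
  st <- simulate_study(simulation_config(
    seed = 53, cells_per_sample = 800, arms = c(placebo = 3L, IL2_2.5 = 3L),
    treg_pre = 0.2, treg_post = c(placebo = 0.2, IL2_1.5 = 0.25, IL2_2.5 = 0.25),
    persistence = c(placebo = 0.4, IL2_1.5 = 0.4, IL2_2.5 = 0.4),
    defect_rates = c(multi_chain = 0, orphan = 0, nonproductive = 0),
    invariant_rate = 0))
  qc <- qc_single_paired(st$chains, st$meta)
  sh <- match_clonotypes(define_clonotype_clusters(qc$cells))
  out_pl <- empirical_transition_matrix(sh, "placebo")$outgoing[["Treg"]]
  out_il <- empirical_transition_matrix(sh, "IL2_2.5")$outgoing[["Treg"]]
  expect_gt(out_pl, out_il)
})
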