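# GLIPH-style motif clustering: trimming, global/local edges, cluster
# building, cross-dataset fractions and logo matrices.

test_that("CDR3 trimming removes conserved flanks and rejects short input", {
  expect_equal(trim_cdr3("CASSLGETQYF"), "SLGET")
  expect_true(is.na(trim_cdr3("CASSQF"))) # length 6: no interior left
  s <- "CASSIRSSYEQYF"
  expect_true(grepl(trim_cdr3(s), s, fixed = TRUE))
})

test_that("global edges require equal length and one exchangeable substitution", {
  e <- global_similarity_edges(c("CASSLGF", "CASSIGF")) # s(L,I) = 2 >= 1
  expect_equal(nrow(e), 1)
  expect_equal(nrow(global_similarity_edges(c("CASS", "CASSL"))), 0)
  expect_equal(nrow(global_similarity_edges(c("CASSDGF", "CASSWGF"))), 0) # s(D,W) = -4
  # identical sequences always edge; two differences never do
  expect_equal(nrow(global_similarity_edges(c("CASSLGF", "CASSLGF"))), 1)
  expect_equal(nrow(global_similarity_edges(c("CASSLGF", "CASIIGF"))), 0)
})

test_that("planted local motifs are mined against the naive background", {
  bg <- with(list(), withr::with_seed(99, simulate_naive_cdr3(5000)))
  query <- withr::with_seed(100, c(
    vapply(rep("SQG", 10), function(m) clonotrack:::plant_motif(m), ""),
    simulate_naive_cdr3(40)))
  hits <- mine_local_motifs(query, background = bg, k_set = 3)
  expect_true("SQG" %in% hits$motif)
  expect_gt(hits$fold[hits$motif == "SQG"], 10)
  expect_lte(hits$p[hits$motif == "SQG"], 1e-3)
})

test_that("motif presence counts once per CDR3", {
  q <- c("CASQGAQGAAYF",  # interior QGAQGA: QGA twice, counts once
         "CAAQGAAAAAYF",  # interior QGAAAA: QGA once
         "CAASSSSSSAYF")  # no QGA
  tab <- clonotrack:::kmer_presence(trim_cdr3(q), 3)
  expect_equal(as.integer(tab[["QGA"]]), 2)
})

test_that("local edges respect the motif position shift limit", {
  hits <- tibble::tibble(motif = "WQV", k = 3, n_query = 3,
                         n_background = 0, fold = Inf, p = 1e-6)
  # trimmed interiors place WQV at positions 0, 2 and 5
  cdr3 <- c("CASWQVAAAAYF", "CASGGWQVAAYF", "CASGGGGGWQVAYF")
  expect_equal(trim_cdr3(cdr3[1]), "WQVAAA")
  e <- local_similarity_edges(cdr3, hits, max_shift = 3)
  key <- paste(pmin(e$a, e$b), pmax(e$a, e$b))
  expect_true("1 2" %in% key)  # shift 2
  expect_true("2 3" %in% key)  # shift 3
  expect_false("1 3" %in% key) # shift 5
  expect_equal(nrow(local_similarity_edges(cdr3[1:2],
                                           hits[0, , drop = FALSE])), 0)
})

test_that("clusters are components of the edge union with deterministic ids", {
  # chain a-b-c via global edges
  entries <- tibble::tibble(cdr3_aa = c("CASSLGF", "CASSIGF", "CASSVGF"),
                            dataset_label = "q")
  cl <- build_motif_clusters(entries, min_report_size = 3,
                             background = withr::with_seed(1, simulate_naive_cdr3(500)))
  expect_equal(nrow(cl$clusters), 3)
  expect_equal(unique(cl$clusters$cluster_size), 3)
  expect_equal(length(unique(cl$clusters$cluster_id)), 1)
  # raising the report threshold never adds clusters
  cl10 <- build_motif_clusters(entries, min_report_size = 10,
                               background = withr::with_seed(1, simulate_naive_cdr3(500)))
  expect_lte(length(unique(cl10$clusters$cluster_id)),
             length(unique(cl$clusters$cluster_id)))
  # input order does not change the grouping
  cl_rev <- build_motif_clusters(entries[3:1, ], min_report_size = 3,
                                 background = withr::with_seed(1, simulate_naive_cdr3(500)))
  expect_equal(sort(cl_rev$clusters$cdr3_aa), sort(cl$clusters$cdr3_aa))
})

test_that("planted motif families are recovered as single clusters", {
  recovered <- vapply(1:20, function(s) {
    sets <- emit_reference_cdr3_sets(n_query = 20, family_size = 10, seed = s)
    entries <- dplyr::bind_rows(sets$query, sets$reference)
    cl <- build_motif_clusters(
      entries, min_report_size = 3,
      background = withr::with_seed(1000 + s, simulate_naive_cdr3(4000)))
    fam <- sets$truth
    # each planted reference family of >= 8 CDR3s forms one cluster
    fam_cdr3 <- split(cl$clusters$cluster_id[match(fam$cdr3_aa[fam$in_reference],
                                                   cl$clusters$cdr3_aa)],
                      fam$family[fam$in_reference])
    all(vapply(fam_cdr3, function(x) length(unique(x)) == 1 && !anyNA(x),
               logical(1)))
  }, logical(1))
  expect_gte(mean(recovered), 0.95)
})

test_that("background-matched queries rarely form clusters (null calibration)", {
  any_cluster <- vapply(1:20, function(s) {
    q <- withr::with_seed(5000 + s, simulate_naive_cdr3(50))
    bg <- withr::with_seed(6000 + s, simulate_naive_cdr3(4000))
    cl <- build_motif_clusters(tibble::tibble(cdr3_aa = q, dataset_label = "q"),
                               min_report_size = 4, background = bg)
    nrow(cl$clusters) > 0
  }, logical(1))
  expect_lte(mean(any_cluster), 0.05)
})

test_that("cross-dataset fraction recovers the planted mixing proportion", {
  sets <- emit_reference_cdr3_sets(n_query = 30, query_in_reference = 0.9,
                                   seed = 11)
  entries <- dplyr::bind_rows(sets$query, sets$reference)
  cl <- build_motif_clusters(entries, min_report_size = 3,
                             background = withr::with_seed(12, simulate_naive_cdr3(4000)))
  frac <- cross_dataset_fraction(cl, "expanded_Treg",
                                 c("athero_ref", "HC_ref"))
  expect_equal(frac, 0.9, tolerance = 0.051)
  frac_athero <- cross_dataset_fraction(cl, "expanded_Treg", "athero_ref")
  expect_equal(frac_athero, 0.9, tolerance = 0.051)
  # all clusters mixed -> 1; query-only clusters -> 0
  mixed <- structure(list(clusters = tibble::tibble(
    cdr3_aa = c("A", "A", "B", "B"), dataset_label = c("q", "r", "q", "r"),
    cluster_id = c("mc1", "mc1", "mc2", "mc2"), cluster_size = 2)),
    class = "motif_clusters")
  expect_equal(cross_dataset_fraction(mixed, "q", "r"), 1)
  lone <- structure(list(clusters = tibble::tibble(
    cdr3_aa = c("A", "B"), dataset_label = "q",
    cluster_id = "mc1", cluster_size = 2)), class = "motif_clusters")
  expect_equal(cross_dataset_fraction(lone, "q", "r"), 0)
  expect_warning(f <- cross_dataset_fraction(lone, "absent", "r"), "undefined")
  expect_true(is.na(f))
})

test_that("position frequency matrices are column-stochastic", {
  pfm <- position_frequency_matrix("CASF")[["4"]]
  expect_equal(unname(pfm["C", 1]), 1) # one-hot
  expect_equal(colSums(pfm), rep(1, 4), ignore_attr = TRUE)
  pfm2 <- position_frequency_matrix(c("CASF", "CAGF"))[["4"]]
  expect_equal(sort(pfm2[c("S", "G"), 3]), c(0.5, 0.5), ignore_attr = TRUE)
  seqs <- withr::with_seed(3, simulate_naive_cdr3(50))
  for (m in position_frequency_matrix(seqs))
    expect_equal(colSums(m), rep(1, ncol(m)), tolerance = 1e-12,
                 ignore_attr = TRUE)
  cp <- position_frequency_matrix(seqs, scheme = "center-pad")
  expect_equal(ncol(cp), max(nchar(seqs)))
  expect_equal(colSums(cp), rep(1, ncol(cp)), tolerance = 1e-12,
               ignore_attr = TRUE)
})
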