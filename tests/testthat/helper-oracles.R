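# Independent oracles and fixture builders shared across the suite.

# BLOSUM62 via Biostrings (shared constants only; alignment code independent)
bl62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Independent global alignment score: Biostrings' C implementation
oracle_align_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  as.numeric(Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = bl62, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global", scoreOnly = TRUE))
}

oracle_distance <- function(a, b, ...) {
  min(oracle_align_score(a, a, ...), oracle_align_score(b, b, ...)) -
    oracle_align_score(a, b, ...)
}

# all-pairs receptor clustering by brute force + union-find; alignment
# scores come from Biostrings in one batched elementwise call per chain,
# deduplicated to unique sequences
oracle_clonotype_partition <- function(alpha, beta, cutoff = 10) {
  n <- length(alpha)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(x, y) {
    rx <- find(x); ry <- find(y)
    if (rx != ry) parent[ry] <<- rx
  }
  pair_d <- function(seqs) {
    uq <- unique(seqs)
    m <- length(uq)
    self <- as.numeric(Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(uq), Biostrings::AAStringSet(uq),
      substitutionMatrix = bl62, gapOpening = 11, gapExtension = 1,
      type = "global", scoreOnly = TRUE))
    d_u <- matrix(0, m, m)
    if (m > 1) {
      ii <- rep(seq_len(m - 1), times = (m - 1):1)
      jj <- unlist(lapply(seq_len(m - 1), function(i) (i + 1):m))
      s <- as.numeric(Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(uq[ii]), Biostrings::AAStringSet(uq[jj]),
        substitutionMatrix = bl62, gapOpening = 11, gapExtension = 1,
        type = "global", scoreOnly = TRUE))
      d <- pmin(self[ii], self[jj]) - s
      d_u[cbind(ii, jj)] <- d
      d_u[cbind(jj, ii)] <- d
    }
    idx <- match(seqs, uq)
    d_u[idx, idx, drop = FALSE]
  }
  da <- pair_d(alpha); db <- pair_d(beta)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (da[i, j] <= cutoff && db[i, j] <= cutoff) union_(i, j)
  vapply(seq_len(n), find, integer(1))
}

# canonical partition representation for label-free comparison
canon_partition <- function(ids) {
  grp <- split(seq_along(ids), ids)
  unname(lapply(grp[order(vapply(grp, min, 1L))], sort))
}

# random receptor fixture with planted near-duplicate families
make_receptor_fixture <- function(n, seed, n_families = 4) {
  withr::with_seed(seed, {
    base_a <- simulate_naive_cdr3(n_families, 11, 15)
    base_b <- simulate_naive_cdr3(n_families, 11, 15)
    mutate1 <- function(s) {
      p <- sample(2:(nchar(s) - 1), 1)
      aa <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 1)
      paste0(substr(s, 1, p - 1), aa, substr(s, p + 1, nchar(s)))
    }
    fam <- sample(n_families, n, replace = TRUE)
    alpha <- vapply(fam, function(f)
      if (runif(1) < 0.5) base_a[f] else mutate1(base_a[f]), "")
    beta <- vapply(fam, function(f)
      if (runif(1) < 0.5) base_b[f] else mutate1(base_b[f]), "")
    # sprinkle unrelated receptors
    lone <- runif(n) < 0.3
    alpha[lone] <- simulate_naive_cdr3(sum(lone), 10, 16)
    beta[lone] <- simulate_naive_cdr3(sum(lone), 10, 16)
    tibble::tibble(cell_id = sprintf("cell%03d", seq_len(n)),
                   alpha_cdr3 = alpha, beta_cdr3 = beta)
  })
}

# minimal clonotype_assignment built directly from a cells tibble (for
# tracking/expansion tests that do not exercise the alignment stage)
make_assignment <- function(cells) {
  sizes <- as.data.frame(table(clonotype_id = cells$clonotype_id),
                         stringsAsFactors = FALSE)
  names(sizes) <- c("clonotype_id", "size")
  structure(list(cells = tibble::as_tibble(cells),
                 clonotypes = tibble::as_tibble(sizes),
                 params = alignment_params()),
            class = "clonotype_assignment")
}

# chains + meta for a set of clean paired cells (QC fixture building)
chains_from_cells <- function(cells) {
  dplyr::bind_rows(
    tibble::tibble(cell_id = cells$cell_id, locus = "TRA",
                   cdr3_aa = cells$alpha_cdr3, cdr3_nt = NA_character_,
                   v_gene = "TRAV2", j_gene = "TRAJ3",
                   productive = TRUE, umis = 1L),
    tibble::tibble(cell_id = cells$cell_id, locus = "TRB",
                   cdr3_aa = cells$beta_cdr3, cdr3_nt = NA_character_,
                   v_gene = "TRBV2", j_gene = "TRBJ1-1",
                   productive = TRUE, umis = 1L))
}

meta_for <- function(cell_ids, patient = "placebo_pt01", timepoint = "pre",
                     arm = "placebo", phenotype = "CD4_naive") {
  tibble::tibble(cell_id = cell_ids, patient_id = patient,
                 timepoint = timepoint, arm = arm, phenotype = phenotype)
}
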