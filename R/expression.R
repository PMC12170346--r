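# Expression-level comparison of expanded vs non-expanded clones:
# expansion labelling, per-gene Wilcoxon differential expression with BH
# adjustment and a log2 fold-change threshold, signal-to-noise GSEA, and
# signature scoring.

#' Label cells as expanded or non-expanded
#'
#' Within the chosen phenotype subset and timepoint, a cell is expanded
#' when its clonotype has at least `min_size` member cells in that same
#' subset/timepoint (within the cell's patient).
#'
#' @param assignment A `clonotype_assignment` with phenotype/timepoint
#'   metadata on its cells (join beforehand or pass `meta`).
#' @param meta Optional metadata tibble joined by `cell_id`.
#' @param subset Phenotype label defining the compartment (default
#'   `"Treg"`).
#' @param timepoint Timepoint to label (default `"post"`).
#' @param min_size Expansion threshold on the within-subset clonotype
#'   size (default 2).
#' @return Tibble `cell_id`, `clonotype_id`, `subset_clone_size`,
#'   `expanded` (logical) for cells of the subset/timepoint.
#' @export
label_expanded <- function(assignment, meta = NULL, subset = "Treg",
                           timepoint = "post", min_size = 2) {
  cells <- assignment$cells
  if (!is.null(meta)) {
    keep <- setdiff(names(meta), setdiff(names(cells), "cell_id"))
    cells <- dplyr::inner_join(cells, meta[keep], by = "cell_id")
  }
  need <- c("phenotype", "timepoint", "patient_id")
  miss <- setdiff(need, names(cells))
  if (length(miss)) abort(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  sub <- cells[cells$phenotype %in% subset & cells$timepoint == timepoint, , drop = FALSE]
  if (nrow(sub) == 0L) abort(sprintf("no '%s' cells at timepoint '%s'",
                                     paste(subset, collapse = "/"), timepoint))
  sub <- sub |>
    dplyr::add_count(.data$patient_id, .data$clonotype_id, name = "subset_clone_size")
  sub$expanded <- sub$subset_clone_size >= min_size
  ct_log("label_expanded: %d expanded, %d non-expanded %s cells at %s",
         sum(sub$expanded), sum(!sub$expanded),
         paste(subset, collapse = "/"), timepoint)
  sub[, c("cell_id", "clonotype_id", "subset_clone_size", "expanded")]
}

# log2 fold change on the expm1 scale with a small guard, the standard
# single-cell convention for log-normalized input
log2fc_expm1 <- function(x1, x2, eps = 1e-9) {
  log2((mean(expm1(x1)) + eps) / (mean(expm1(x2)) + eps))
}

#' Wilcoxon differential expression between expanded and non-expanded cells
#'
#' Per-gene two-sided Wilcoxon rank-sum test (normal approximation with
#' tie correction) with Benjamini-Hochberg adjustment over all tested
#' genes. Fold changes are computed on the de-logged scale:
#' `log2FC = log2((mean(expm1(x1)) + eps) / (mean(expm1(x2)) + eps))`.
#' Genes detected in fewer than `min_cells` cells overall are excluded
#' before testing. A gene is `significant` when `q < 0.05` and
#' `|log2fc| > 0.3`.
#'
#' @param expr Cells x genes matrix of log-normalized expression
#'   (rows = cells, named columns = genes).
#' @param labels Logical or factor-like vector per cell: `TRUE`/first
#'   level = group 1 (expanded), `FALSE`/second = group 2.
#' @param min_cells Minimum cells expressing a gene (> 0) to test it
#'   (default 3).
#' @param fc_threshold Absolute log2 fold-change threshold for the
#'   significance flag (default 0.3).
#' @param q_threshold BH-adjusted p threshold (default 0.05).
#' @return Tibble of DGE records: `gene`, `log2fc`, `p`, `q`,
#'   `significant`, sorted by `p`.
#' @export
differential_expression <- function(expr, labels, min_cells = 3,
                                    fc_threshold = 0.3, q_threshold = 0.05) {
  expr <- as.matrix(expr)
  if (is.null(colnames(expr))) abort("expr must have gene names as colnames")
  if (length(labels) != nrow(expr)) abort("one label per cell (row) required")
  g1 <- as.logical(labels)
  if (sum(g1) < 3L || sum(!g1) < 3L) abort("each group needs at least 3 cells")
  detected <- colSums(expr > 0) >= min_cells
  if (!any(detected)) abort("no genes pass the detection filter")
  expr <- expr[, detected, drop = FALSE]
  x1 <- expr[g1, , drop = FALSE]
  x2 <- expr[!g1, , drop = FALSE]
  p <- vapply(seq_len(ncol(expr)), function(j) {
    suppressWarnings(wilcox.test(x1[, j], x2[, j],
                                 exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1 # constant genes
  l2fc <- vapply(seq_len(ncol(expr)),
                 function(j) log2fc_expm1(x1[, j], x2[, j]), numeric(1))
  q <- benjamini_hochberg(p)
  out <- tibble(gene = colnames(expr), log2fc = l2fc, p = p, q = q,
                significant = q < q_threshold & abs(l2fc) > fc_threshold)
  dplyr::arrange(out, .data$p, .data$gene)
}

# signal-to-noise ranking metric with the GSEA variance floor:
# sd floored at 0.2 * |mean| (0.2 when the mean is 0)
signal_to_noise <- function(x1, x2) {
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  s1 <- apply(x1, 2, sd); s2 <- apply(x2, 2, sd)
  floor_sd <- function(s, m) pmax(s, ifelse(abs(m) > 0, 0.2 * abs(m), 0.2))
  (m1 - m2) / (floor_sd(s1, m1) + floor_sd(s2, m2))
}

# weighted KS running-sum enrichment score (weight = |metric|, power 1)
enrichment_score <- function(ranked_metric, in_set) {
  nr <- sum(abs(ranked_metric[in_set]))
  n <- length(ranked_metric)
  nh <- sum(in_set)
  if (nh == 0L || nh == n || nr == 0) return(0)
  step <- ifelse(in_set, abs(ranked_metric) / nr, -1 / (n - nh))
  run <- cumsum(step)
  run[which.max(abs(run))]
}

#' Signal-to-noise GSEA between two cell groups
#'
#' Genes are ranked by the signal-to-noise ratio
#' `(mu1 - mu2) / (sigma1 + sigma2)` (standard deviations floored at
#' `0.2 |mu|`); the enrichment score is the extremum of the weighted
#' running sum (weights `|metric|`, power 1). Normalization and FDR
#' q-values come from permutations: phenotype (label) permutation when
#' both groups have at least 15 cells, otherwise gene-set (random-set)
#' permutation.
#'
#' @param expr Cells x genes log-normalized matrix.
#' @param labels Logical per cell (`TRUE` = group 1).
#' @param gene_sets Named list of gene-name vectors.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @param min_set_size Smallest usable gene set after intersection with
#'   the matrix (default 5).
#' @return Tibble: `gene_set`, `es`, `nes`, `p`, `q`, `size`,
#'   `leading_edge` (list column), `permutation` type.
#' @export
gsea_signal_to_noise <- function(expr, labels, gene_sets, n_perm = 1000,
                                 seed = 1, min_set_size = 5) {
  expr <- as.matrix(expr)
  g1 <- as.logical(labels)
  if (length(unique(g1)) < 2L) abort("labels are degenerate (single group)")
  genes <- colnames(expr)
  gene_sets <- lapply(gene_sets, intersect, genes)
  gene_sets <- gene_sets[lengths(gene_sets) >= min_set_size]
  if (!length(gene_sets)) abort("no gene set of sufficient size present in the matrix")

  metric <- signal_to_noise(expr[g1, , drop = FALSE], expr[!g1, , drop = FALSE])
  ord <- order(metric, decreasing = TRUE)
  ranked <- metric[ord]
  ranked_genes <- genes[ord]

  es_of <- function(set, rm = ranked, rg = ranked_genes)
    enrichment_score(rm, rg %in% set)
  es_obs <- vapply(gene_sets, es_of, numeric(1))

  use_pheno <- sum(g1) >= 15L && sum(!g1) >= 15L
  perm_es <- matrix(NA_real_, n_perm, length(gene_sets))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      if (use_pheno) {
        gp <- sample(g1)
        m <- signal_to_noise(expr[gp, , drop = FALSE], expr[!gp, , drop = FALSE])
        o <- order(m, decreasing = TRUE)
        perm_es[b, ] <- vapply(gene_sets, es_of, numeric(1),
                               rm = m[o], rg = genes[o])
      } else {
        perm_es[b, ] <- vapply(lengths(gene_sets), function(sz)
          enrichment_score(ranked, seq_along(ranked) %in% sample(length(ranked), sz)),
          numeric(1))
      }
    }
  })

  nes <- p <- numeric(length(gene_sets))
  for (s in seq_along(gene_sets)) {
    same_sign <- perm_es[, s][sign(perm_es[, s]) == sign(es_obs[s])]
    denom <- if (length(same_sign)) mean(abs(same_sign)) else mean(abs(perm_es[, s]))
    nes[s] <- if (denom > 0) es_obs[s] / denom else 0
    p[s] <- (1 + sum(abs(perm_es[, s]) >= abs(es_obs[s]))) / (1 + n_perm)
  }
  leading <- lapply(seq_along(gene_sets), function(s) {
    in_set <- ranked_genes %in% gene_sets[[s]]
    nr <- sum(abs(ranked[in_set]))
    step <- ifelse(in_set, abs(ranked) / nr, -1 / (length(ranked) - sum(in_set)))
    run <- cumsum(step)
    peak <- which.max(abs(run))
    if (es_obs[s] >= 0) ranked_genes[seq_len(peak)][in_set[seq_len(peak)]]
    else ranked_genes[peak:length(run)][in_set[peak:length(run)]]
  })
  out <- tibble(gene_set = names(gene_sets), es = unname(es_obs),
                nes = unname(nes), p = unname(p),
                q = benjamini_hochberg(p), size = lengths(gene_sets),
                leading_edge = leading,
                permutation = if (use_pheno) "phenotype" else "gene-set")
  dplyr::arrange(out, .data$p, .data$gene_set)
}

#' Per-cell signature score
#'
#' Mean over the listed genes of the z-scored (across cells)
#' log-normalized expression. Zero-variance and absent genes are excluded
#' (logged); erroring only when no listed gene is usable.
#'
#' @param expr Cells x genes log-normalized matrix.
#' @param genes Character vector of signature genes.
#' @return Numeric vector of per-cell scores (named by rownames of
#'   `expr`); attribute `genes_used`.
#' @export
signature_score <- function(expr, genes) {
  expr <- as.matrix(expr)
  present <- intersect(genes, colnames(expr))
  if (length(present) < length(genes))
    ct_log("signature_score: %d gene(s) absent from the matrix",
           length(genes) - length(present))
  if (!length(present)) abort("none of the signature genes are present")
  sub <- expr[, present, drop = FALSE]
  sds <- apply(sub, 2, sd)
  if (any(sds == 0)) {
    ct_log("signature_score: %d constant gene(s) excluded", sum(sds == 0))
    sub <- sub[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (!ncol(sub)) abort("all signature genes are constant")
  z <- scale(sub)
  score <- rowMeans(z)
  attr(score, "genes_used") <- colnames(sub)
  score
}

#' Read gene sets from a GMT file
#' @param path Path to a tab-separated GMT file (set name, description,
#'   genes...).
#' @return Named list of gene vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  parts <- strsplit(lines, "\t")
  setNames(lapply(parts, function(x) x[-(1:2)]),
           vapply(parts, `[`, "", 1))
}

#' Write an expression matrix as MatrixMarket + gene/cell TSVs
#' @param expr Cells x genes matrix.
#' @param dir Output directory (created if needed); writes
#'   `matrix.mtx` (genes x cells, MatrixMarket), `genes.tsv`,
#'   `barcodes.tsv`.
#' @export
write_expression_mtx <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(as.matrix(expr)), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(expr), file.path(dir, "genes.tsv"))
  writeLines(rownames(expr), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read an expression matrix written by [write_expression_mtx()]
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`.
#' @return Dense cells x genes matrix.
#' @export
read_expression_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  out <- t(as.matrix(m))
  dimnames(out) <- list(cells, genes)
  out
}
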