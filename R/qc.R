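# QC funnel: reduce raw chain tables to cells with a single paired
# productive alpha/beta receptor, remove invariant (MAIT/iNKT-like) TCRs,
# and account for every input cell in a QCReport.

#' Default invariant-TCR removal rules
#'
#' Alpha-chain V/J combinations treated as invariant T cells:
#' MAIT-like (TRAV1-2 with TRAJ33/TRAJ20/TRAJ12) and iNKT-like
#' (TRAV10 with TRAJ18). The rule list is a convention, not a registry;
#' override it to match the annotation in use.
#'
#' @return A data frame with columns `v_gene`, `j_gene`.
#' @export
default_invariant_rules <- function() {
  data.frame(
    v_gene = c("TRAV1-2", "TRAV1-2", "TRAV1-2", "TRAV10"),
    j_gene = c("TRAJ33", "TRAJ20", "TRAJ12", "TRAJ18"),
    stringsAsFactors = FALSE
  )
}

#' QC to single-paired productive alpha/beta cells
#'
#' Classifies every input cell into exactly one category:
#' * `single_paired` - exactly one productive TRA and one productive TRB
#'   (additional non-productive chains are ignored); kept.
#' * `multi_chain` - two or more productive chains of the same locus.
#' * `orphan` - productive chains of only one of TRA/TRB.
#' * `nonproductive_only` - no productive TRA/TRB chain at all.
#' * `invariant_removed` - single-paired cells whose alpha V/J matches an
#'   invariant rule; removed after pairing.
#' Cells whose barcode has no metadata row are dropped with a warning and
#' counted separately.
#'
#' @param chains Chain tibble (internal layout, see [read_airr()]).
#' @param meta Cell metadata tibble.
#' @param invariant_rules Data frame of alpha `v_gene`/`j_gene` pairs to
#'   remove; `NULL` disables invariant removal.
#' @return A list with `cells` (one row per kept cell: `cell_id`,
#'   `alpha_cdr3`, `beta_cdr3`, alpha/beta V and J genes, metadata
#'   columns) and `report` (a `qc_report`).
#' @export
qc_single_paired <- function(chains, meta,
                             invariant_rules = default_invariant_rules()) {
  if (!is.data.frame(chains) || nrow(chains) == 0L) abort("no chains supplied")
  chains <- as_tibble(chains)
  meta <- validate_cell_meta(as_tibble(meta))

  in_meta <- chains$cell_id %in% meta$cell_id
  n_unmatched <- length(unique(chains$cell_id[!in_meta]))
  if (n_unmatched > 0) {
    warn(sprintf("%d cell barcode(s) missing from metadata; dropped", n_unmatched))
    chains <- chains[in_meta, , drop = FALSE]
  }
  if (nrow(chains) == 0L) abort("no chains left after metadata matching")

  per_cell <- chains |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      n_tra = sum(.data$locus == "TRA" & .data$productive),
      n_trb = sum(.data$locus == "TRB" & .data$productive),
      .groups = "drop")
  per_cell$category <- with(per_cell, ifelse(
    n_tra == 0 & n_trb == 0, "nonproductive_only", ifelse(
      n_tra >= 2 | n_trb >= 2, "multi_chain", ifelse(
        n_tra == 0 | n_trb == 0, "orphan", "single_paired"))))

  paired_ids <- per_cell$cell_id[per_cell$category == "single_paired"]
  prod <- chains[chains$productive & chains$locus %in% c("TRA", "TRB") &
                   chains$cell_id %in% paired_ids, , drop = FALSE]
  alpha <- prod[prod$locus == "TRA", c("cell_id", "cdr3_aa", "v_gene", "j_gene")]
  beta <- prod[prod$locus == "TRB", c("cell_id", "cdr3_aa", "v_gene", "j_gene")]
  names(alpha) <- c("cell_id", "alpha_cdr3", "alpha_v", "alpha_j")
  names(beta) <- c("cell_id", "beta_cdr3", "beta_v", "beta_j")
  cells <- dplyr::inner_join(alpha, beta, by = "cell_id")

  # drop paired cells with empty/invalid CDR3s (cannot be clonotyped)
  ok <- !is.na(cells$alpha_cdr3) & !is.na(cells$beta_cdr3) &
    nchar(cells$alpha_cdr3) > 0 & nchar(cells$beta_cdr3) > 0
  if (any(!ok)) {
    warn(sprintf("%d paired cell(s) with empty CDR3 dropped", sum(!ok)))
    per_cell$category[per_cell$cell_id %in% cells$cell_id[!ok]] <- "nonproductive_only"
    cells <- cells[ok, , drop = FALSE]
  }

  n_invariant <- 0L
  if (!is.null(invariant_rules) && nrow(invariant_rules) > 0) {
    inv_key <- paste(invariant_rules$v_gene, invariant_rules$j_gene)
    is_inv <- paste(cells$alpha_v, cells$alpha_j) %in% inv_key
    n_invariant <- sum(is_inv)
    if (n_invariant > 0) {
      ct_log("qc: removing %d invariant TCR cell(s)", n_invariant)
      per_cell$category[per_cell$cell_id %in% cells$cell_id[is_inv]] <- "invariant_removed"
      cells <- cells[!is_inv, , drop = FALSE]
    }
  }

  cells <- dplyr::inner_join(cells, meta, by = "cell_id")

  n_input <- nrow(per_cell) + n_unmatched
  counts <- c(
    n_single_paired = sum(per_cell$category == "single_paired"),
    n_multi_chain = sum(per_cell$category == "multi_chain"),
    n_orphan = sum(per_cell$category == "orphan"),
    n_nonproductive_only = sum(per_cell$category == "nonproductive_only"),
    n_invariant_removed = sum(per_cell$category == "invariant_removed"),
    n_no_metadata = n_unmatched
  )
  report <- structure(
    c(list(n_input_cells = n_input), as.list(counts),
      list(fractions = counts / n_input)),
    class = "qc_report")
  stopifnot(sum(counts) == n_input)
  ct_log("qc: %d input cells -> %d single-paired (%.1f%%)",
         n_input, counts[["n_single_paired"]],
         100 * counts[["n_single_paired"]] / n_input)
  list(cells = as_tibble(cells), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  input cells:          %d\n", x$n_input_cells))
  for (f in c("n_single_paired", "n_multi_chain", "n_orphan",
              "n_nonproductive_only", "n_invariant_removed", "n_no_metadata"))
    cat(sprintf("  %-21s %d (%.2f%%)\n", paste0(sub("^n_", "", f), ":"),
                x[[f]], 100 * x$fractions[[paste0(f)]]))
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report A `qc_report`.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' V/J gene segment usage and pairing tables
#'
#' @param cells QC-passed cell tibble (from [qc_single_paired()]).
#' @return A list of tibbles: `alpha_v`, `alpha_j`, `beta_v`, `beta_j`
#'   (gene, count, frequency; sorted descending), `alpha_vj`, `beta_vj`
#'   (V-J pairing counts) and `alpha_beta_v` (alpha-V x beta-V pairing
#'   counts).
#' @export
gene_usage <- function(cells) {
  if (!is.data.frame(cells) || nrow(cells) == 0L) abort("no cells supplied")
  freq_tab <- function(x, name) {
    out <- as_tibble(as.data.frame(table(gene = x), stringsAsFactors = FALSE))
    names(out) <- c("gene", "count")
    out$frequency <- out$count / sum(out$count)
    dplyr::arrange(out, dplyr::desc(.data$count), .data$gene)
  }
  pair_tab <- function(a, b, na, nb) {
    out <- as_tibble(as.data.frame(table(a = a, b = b), stringsAsFactors = FALSE))
    names(out) <- c(na, nb, "count")
    out[out$count > 0, , drop = FALSE]
  }
  list(
    alpha_v = freq_tab(cells$alpha_v),
    alpha_j = freq_tab(cells$alpha_j),
    beta_v = freq_tab(cells$beta_v),
    beta_j = freq_tab(cells$beta_j),
    alpha_vj = pair_tab(cells$alpha_v, cells$alpha_j, "v_gene", "j_gene"),
    beta_vj = pair_tab(cells$beta_v, cells$beta_j, "v_gene", "j_gene"),
    alpha_beta_v = pair_tab(cells$alpha_v, cells$beta_v, "alpha_v", "beta_v")
  )
}
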