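# Longitudinal clonotype tracking: the clonotype is used as a barcode to
# relate cells (not individual cells) across the pre/post timepoints of a
# patient; phenotype changes among clonally related cells are then read
# from transition tables and empirical transition matrices.

#' Default CD4 phenotype collapse used for tracking
#'
#' Maps the full phenotype label set onto the four CD4 tracking states
#' Treg, Tcm, Tem, naive; CD8 labels are excluded (NA).
#' @return Named character vector phenotype -> collapsed state.
#' @export
cd4_collapse_map <- function() {
  c(Treg = "Treg", CD4_Tcm = "Tcm", CD4_Tem = "Tem", CD4_naive = "naive")
}

#' Match clonotypes across timepoints within patients
#'
#' A clonotype is shared for a patient when it has at least one member
#' cell at both the pre and the post timepoint. Patients missing a
#' timepoint are excluded with a warning.
#'
#' @param assignment A `clonotype_assignment` whose cells carry
#'   `patient_id`, `timepoint`, `arm` and `phenotype` columns (metadata can
#'   be joined beforehand or supplied via `meta`).
#' @param meta Optional metadata tibble to join by `cell_id`.
#' @return A list of class `shared_clonotypes`:
#'   * `cells` - tracked cell table with a `shared` flag,
#'   * `by_patient` - per patient: pre-only / shared / post-only clonotype
#'     counts, shared and total cell counts,
#'   * `by_arm` - the same aggregated per arm, with
#'     `shared_cell_fraction = n_shared_cells / total_cells`.
#' @export
match_clonotypes <- function(assignment, meta = NULL) {
  cells <- assignment$cells
  if (!is.null(meta)) {
    keep <- setdiff(names(meta), setdiff(names(cells), "cell_id"))
    cells <- dplyr::inner_join(cells, meta[keep], by = "cell_id")
  }
  need <- c("patient_id", "timepoint", "arm")
  miss <- setdiff(need, names(cells))
  if (length(miss)) abort(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))

  tp_by_pat <- cells |>
    dplyr::distinct(.data$patient_id, .data$timepoint) |>
    dplyr::count(.data$patient_id)
  incomplete <- tp_by_pat$patient_id[tp_by_pat$n < 2L]
  if (length(incomplete)) {
    warn(sprintf("patient(s) missing a timepoint, excluded from tracking: %s",
                 paste(incomplete, collapse = ", ")))
    cells <- cells[!cells$patient_id %in% incomplete, , drop = FALSE]
  }
  if (nrow(cells) == 0L) abort("no patients with both timepoints")

  occ <- cells |>
    dplyr::distinct(.data$patient_id, .data$clonotype_id, .data$timepoint)
  shared_keys <- occ |>
    dplyr::count(.data$patient_id, .data$clonotype_id) |>
    dplyr::filter(.data$n == 2L)
  cells$shared <- paste(cells$patient_id, cells$clonotype_id) %in%
    paste(shared_keys$patient_id, shared_keys$clonotype_id)

  by_patient <- cells |>
    dplyr::group_by(.data$arm, .data$patient_id) |>
    dplyr::summarise(
      n_shared_clonotypes = dplyr::n_distinct(.data$clonotype_id[.data$shared]),
      n_pre_only = dplyr::n_distinct(
        .data$clonotype_id[!.data$shared & .data$timepoint == "pre"]),
      n_post_only = dplyr::n_distinct(
        .data$clonotype_id[!.data$shared & .data$timepoint == "post"]),
      n_shared_cells = sum(.data$shared),
      total_cells = dplyr::n(),
      .groups = "drop")

  by_arm <- by_patient |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), sum), .groups = "drop") |>
    dplyr::mutate(shared_cell_fraction = .data$n_shared_cells / .data$total_cells)

  structure(list(cells = cells, by_patient = by_patient, by_arm = by_arm),
            class = "shared_clonotypes")
}

#' Chi-squared tests of shared-cell proportions between arms
#'
#' For each treated arm versus the reference arm, a 2 x 2 chi-squared test
#' on (shared vs non-shared cells) x arm, plus a global arms x 2 test.
#'
#' @param shared A `shared_clonotypes` object.
#' @param reference Reference arm label (default `"placebo"`).
#' @return A named list of `ct_test_result`s (one per treated arm, plus
#'   `global`).
#' @export
shared_fraction_test <- function(shared, reference = "placebo") {
  ba <- shared$by_arm
  if (nrow(ba) < 2L) abort("need at least two arms")
  if (!reference %in% ba$arm) abort(sprintf("reference arm '%s' not present", reference))
  mk_row <- function(a) {
    r <- ba[ba$arm == a, ]
    c(shared = r$n_shared_cells, nonshared = r$total_cells - r$n_shared_cells)
  }
  out <- list()
  for (a in setdiff(ba$arm, reference)) {
    tab <- rbind(mk_row(reference), mk_row(a))
    rownames(tab) <- c(reference, a)
    out[[a]] <- chi2_independence(tab)
  }
  gl <- t(vapply(ba$arm, mk_row, numeric(2)))
  rownames(gl) <- ba$arm
  out$global <- chi2_independence(gl)
  out
}

# per-clonotype pre/post phenotype multisets (collapsed), one row per
# (patient, clonotype); cells with labels outside the collapse map drop out
tracked_phenotypes <- function(shared, collapse_map) {
  cells <- shared$cells[shared$cells$shared, , drop = FALSE]
  cells$state <- unname(collapse_map[cells$phenotype])
  cells <- cells[!is.na(cells$state), , drop = FALSE]
  cells
}

#' Phenotype transition table for tracked clonotypes
#'
#' Among shared clonotypes of one arm (optionally only those with at least
#' one cell of a `restrict_to` state at either timepoint), counts cells by
#' collapsed phenotype at pre (row 1) and post (row 2).
#'
#' @param shared A `shared_clonotypes` object.
#' @param arm Arm label to tabulate.
#' @param restrict_to Optional collapsed state (e.g. `"Treg"`); keeps only
#'   clonotypes touching that state at either timepoint.
#' @param collapse_map Phenotype collapse, default [cd4_collapse_map()].
#' @return A `contingency_table` (2 x K, rows pre/post), or an empty
#'   0 x K table when nothing is tracked.
#' @export
build_transition_table <- function(shared, arm, restrict_to = NULL,
                                   collapse_map = cd4_collapse_map()) {
  cells <- tracked_phenotypes(shared, collapse_map)
  cells <- cells[cells$arm == arm, , drop = FALSE]
  states <- unique(unname(collapse_map))
  if (!is.null(restrict_to)) {
    key <- paste(cells$patient_id, cells$clonotype_id)
    touch <- unique(key[cells$state %in% restrict_to])
    cells <- cells[key %in% touch, , drop = FALSE]
  }
  if (nrow(cells) == 0L) {
    m <- matrix(0L, nrow = 2, ncol = length(states),
                dimnames = list(c("pre", "post"), states))
    attr(m, "empty") <- TRUE
    return(m)
  }
  tab <- table(factor(cells$timepoint, levels = c("pre", "post")),
               factor(cells$state, levels = states))
  contingency_table(matrix(as.integer(tab), nrow = 2L),
                    row_labels = c("pre", "post"), col_labels = states)
}

#' Exact significance of a phenotype transition table
#'
#' Drops all-zero phenotype columns and applies the exact r x c Fisher
#' test to the remaining 2 x K table.
#'
#' @param table Transition table from [build_transition_table()].
#' @return Exact two-sided p-value.
#' @export
transition_significance <- function(table) {
  if (isTRUE(attr(table, "empty"))) abort("empty transition table")
  m <- unclass(table)
  m <- m[, colSums(m) > 0, drop = FALSE]
  fisher_exact_rxc(m)
}

#' Empirical phenotype transition matrix from tracked clonotypes
#'
#' For each shared clonotype with `n_pre` and `n_post` cells, every
#' (pre-cell, post-cell) phenotype pair contributes weight
#' `1 / (n_pre * n_post)` (per-clonotype weighting: each clonotype counts
#' once) or weight 1 (`per-pair`). Accumulated counts are row-normalized;
#' source states with no tracked cells get `NA` rows (flagged, not
#' zero-filled).
#'
#' @param shared A `shared_clonotypes` object.
#' @param arm Arm label.
#' @param weighting `"per-clonotype"` (default) or `"per-pair"`.
#' @param collapse_map Phenotype collapse, default [cd4_collapse_map()].
#' @return List with `matrix` (K x K row-stochastic, NA rows where the
#'   source state is unobserved), `outgoing` (1 - diagonal), `weights`
#'   (unnormalized accumulated flow) and `weighting`.
#' @export
empirical_transition_matrix <- function(shared, arm,
                                        weighting = c("per-clonotype", "per-pair"),
                                        collapse_map = cd4_collapse_map()) {
  weighting <- match.arg(weighting)
  cells <- tracked_phenotypes(shared, collapse_map)
  cells <- cells[cells$arm == arm, , drop = FALSE]
  states <- unique(unname(collapse_map))
  K <- length(states)
  W <- matrix(0, K, K, dimnames = list(states, states))
  if (nrow(cells)) {
    key <- paste(cells$patient_id, cells$clonotype_id)
    for (k in unique(key)) {
      cl <- cells[key == k, , drop = FALSE]
      pre <- cl$state[cl$timepoint == "pre"]
      post <- cl$state[cl$timepoint == "post"]
      if (!length(pre) || !length(post)) next # collapse removed one side
      w <- if (weighting == "per-clonotype") 1 / (length(pre) * length(post)) else 1
      for (i in pre) for (j in post) W[i, j] <- W[i, j] + w
    }
  }
  rs <- rowSums(W)
  M <- W / ifelse(rs > 0, rs, NA_real_)
  outgoing <- 1 - diag(M)
  names(outgoing) <- states
  list(matrix = M, outgoing = outgoing, weights = W, weighting = weighting,
       undefined_rows = states[rs == 0])
}

#' Sankey-style link list of tracked phenotype flow
#'
#' @param shared A `shared_clonotypes` object.
#' @param arm Arm label.
#' @param weighting As in [empirical_transition_matrix()].
#' @param collapse_map Phenotype collapse.
#' @param path Optional CSV output path.
#' @return Tibble (source, target, weight); weights sum to the tracked
#'   flow (number of tracked clonotypes under per-clonotype weighting).
#' @export
export_sankey <- function(shared, arm, weighting = "per-clonotype",
                          collapse_map = cd4_collapse_map(), path = NULL) {
  tm <- empirical_transition_matrix(shared, arm, weighting, collapse_map)
  W <- tm$weights
  idx <- which(W > 0, arr.ind = TRUE)
  links <- tibble(source = rownames(W)[idx[, 1]],
                  target = colnames(W)[idx[, 2]],
                  weight = W[idx])
  links <- dplyr::arrange(links, .data$source, .data$target)
  if (!is.null(path)) readr::write_csv(links, path, progress = FALSE)
  links
}
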