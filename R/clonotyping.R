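# Clonotype definition by CDR3 alignment distance over both receptor arms.
#
# Receptors (unique alpha/beta CDR3 pairs) are joined when BOTH chains lie
# within an alignment-distance cutoff; clonotypes are the connected
# components of that graph, mapped back to cells.

#' Alignment parameters for clonotype definition
#'
#' @param substitution_matrix Name of the substitution matrix; only
#'   `"BLOSUM62"` is bundled.
#' @param gap_open,gap_extend Positive affine gap penalties; a gap of
#'   length L costs `gap_open + gap_extend * L`.
#' @param cutoff Non-negative distance cutoff in score units; two chains
#'   are "highly similar" when their distance is at most this value.
#' @param arms `"AND"` joins receptors only when both alpha and beta
#'   distances pass the cutoff (default); `"sum"` uses the combined
#'   alpha + beta distance against `2 * cutoff`.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_open = 11, gap_extend = 1,
                             cutoff = 10, arms = c("AND", "sum")) {
  if (!identical(substitution_matrix, "BLOSUM62"))
    abort("only BLOSUM62 is available")
  if (gap_open <= 0 || gap_extend <= 0) abort("gap penalties must be positive")
  if (cutoff < 0) abort("cutoff must be >= 0")
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 cutoff = cutoff, arms = match.arg(arms)),
            class = "alignment_params")
}

# BLOSUM62 (from Biostrings' data object), cached per session
blosum62 <- function() {
  if (is.null(.ct_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .ct_cache$blosum62 <- e$BLOSUM62
  }
  .ct_cache$blosum62
}

# encode aa strings as 0-based integer codes into the BLOSUM62 row order
encode_aa <- function(seqs, validate = TRUE) {
  alpha <- rownames(blosum62())
  lapply(seqs, function(s) {
    res <- strsplit(s, "")[[1]]
    if (validate) {
      bad <- which(!res %in% AA20)
      if (length(bad))
        abort(sprintf("invalid residue '%s' at position %d of '%s'",
                      res[bad[1]], bad[1], s))
    }
    match(res, alpha) - 1L
  })
}

#' Global alignment score of two amino-acid sequences
#'
#' Optimal end-to-end (Needleman-Wunsch/Gotoh) alignment score under the
#' configured substitution matrix and affine gap costs.
#'
#' @param a,b Amino-acid strings over the 20-letter alphabet.
#' @param params An [alignment_params()] object.
#' @return Integer-valued alignment score.
#' @export
#' @examples
#' global_alignment_score("CASS", "CASS") # 21
global_alignment_score <- function(a, b, params = alignment_params()) {
  check_aa(a, "a"); check_aa(b, "b")
  enc <- encode_aa(c(a, b), validate = FALSE)
  cpp_align_scores(enc[1], enc[2], blosum62(),
                   params$gap_open, params$gap_extend)[1]
}

#' Alignment distance between two CDR3 sequences
#'
#' `d(a, b) = min(S(a, a), S(b, b)) - S(a, b)`, where S is the global
#' alignment score. The distance is symmetric, non-negative for BLOSUM62
#' and zero on identical sequences, so the clonotype cutoff is read
#' directly in score units.
#'
#' @inheritParams global_alignment_score
#' @return Non-negative distance.
#' @export
#' @examples
#' receptor_distance("CASSL", "CASSV") # 3
receptor_distance <- function(a, b, params = alignment_params()) {
  saa <- global_alignment_score(a, a, params)
  sbb <- global_alignment_score(b, b, params)
  sab <- global_alignment_score(a, b, params)
  min(saa, sbb) - sab
}

# distance edges (d <= cutoff) among a unique character vector of CDR3s
distance_edges <- function(seqs, params, cutoff = params$cutoff) {
  enc <- encode_aa(seqs)
  max_ld <- as.integer(floor(cutoff / params$gap_extend))
  df <- cpp_distance_edges(enc, blosum62(), params$gap_open,
                           params$gap_extend, cutoff, max_ld)
  as_tibble(df)
}

#' Define clonotype clusters from paired CDR3 sequences
#'
#' Deduplicates cells to unique (alpha, beta) CDR3 pairs, links two
#' receptors when the alpha-alpha and beta-beta alignment distances are
#' both within the cutoff (or, with `arms = "sum"`, when their sum is
#' within twice the cutoff), and takes connected components as clonotypes.
#' V-gene matching is not enforced. Clonotype ids are deterministic:
#' components are ranked by descending cell count, ties broken by the
#' lexicographically smallest beta then alpha CDR3.
#'
#' @param cells Tibble of QC-passing cells with columns `cell_id`,
#'   `alpha_cdr3`, `beta_cdr3` (as produced by [qc_single_paired()];
#'   extra columns are carried through).
#' @param params [alignment_params()].
#' @return A list of class `clonotype_assignment`:
#'   `cells` (cell_id, clonotype_id), `clonotypes` (clonotype_id, size,
#'   n_receptors, representative alpha/beta CDR3, patient set and private
#'   flag when patient metadata is present), and the `params` used.
#' @export
define_clonotype_clusters <- function(cells, params = alignment_params()) {
  if (!is.data.frame(cells) || nrow(cells) == 0L) abort("no cells supplied")
  need <- c("cell_id", "alpha_cdr3", "beta_cdr3")
  miss <- setdiff(need, names(cells))
  if (length(miss)) abort(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))

  rec <- dplyr::distinct(as_tibble(cells[need[-1]]))
  rec$rid <- seq_len(nrow(rec))
  ua <- unique(rec$alpha_cdr3)
  ub <- unique(rec$beta_cdr3)
  rec$aidx <- match(rec$alpha_cdr3, ua)
  rec$bidx <- match(rec$beta_cdr3, ub)
  ct_log("clonotyping: %d cells, %d unique receptors (%d alpha, %d beta)",
         nrow(cells), nrow(rec), length(ua), length(ub))

  if (params$arms == "AND") {
    ea <- distance_edges(ua, params)
    eb <- distance_edges(ub, params)
    edges <- receptor_edges_and(rec, ea, eb)
  } else {
    # combined alpha+beta distance <= 2 * cutoff: per-chain distance can use
    # the full combined budget, so mine chain edges at the doubled cutoff
    ea <- distance_edges(ua, params, cutoff = 2 * params$cutoff)
    eb <- distance_edges(ub, params, cutoff = 2 * params$cutoff)
    edges <- receptor_edges_sum(rec, ea, eb, 2 * params$cutoff)
  }

  g <- igraph::graph_from_data_frame(
    edges[, c("rid1", "rid2")],
    directed = FALSE,
    vertices = data.frame(name = as.character(rec$rid)))
  comp <- igraph::components(g)$membership[as.character(rec$rid)]
  rec$comp <- as.integer(comp)

  cells_out <- as_tibble(cells)
  cells_out$.comp <- rec$comp[match(paste(cells_out$alpha_cdr3, cells_out$beta_cdr3),
                                    paste(rec$alpha_cdr3, rec$beta_cdr3))]

  # deterministic ids: by descending cell count, then smallest beta/alpha CDR3
  summ <- cells_out |>
    dplyr::count(.data$.comp, name = "size") |>
    dplyr::left_join(
      rec |>
        dplyr::group_by(.data$comp) |>
        dplyr::summarise(rep_beta = min(.data$beta_cdr3),
                         rep_alpha = min(.data$alpha_cdr3),
                         n_receptors = dplyr::n()),
      by = c(".comp" = "comp")) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$rep_beta, .data$rep_alpha)
  summ$clonotype_id <- make_ids("ct", nrow(summ))

  cells_out$clonotype_id <- summ$clonotype_id[match(cells_out$.comp, summ$.comp)]
  cells_out$.comp <- NULL

  clonotypes <- summ[, c("clonotype_id", "size", "n_receptors",
                         "rep_beta", "rep_alpha")]
  if ("patient_id" %in% names(cells_out)) {
    pat <- cells_out |>
      dplyr::group_by(.data$clonotype_id) |>
      dplyr::summarise(patients = list(sort(unique(.data$patient_id))))
    clonotypes <- dplyr::left_join(clonotypes, pat, by = "clonotype_id")
    clonotypes$private <- lengths(clonotypes$patients) == 1L
  }

  structure(list(cells = cells_out[, c("cell_id", "clonotype_id",
                                       setdiff(names(cells_out),
                                               c("cell_id", "clonotype_id")))],
                 clonotypes = clonotypes, params = params),
            class = "clonotype_assignment")
}

# receptors joined iff both chains within cutoff (AND rule)
receptor_edges_and <- function(rec, ea, eb) {
  dt <- data.table::as.data.table(rec[, c("rid", "aidx", "bidx")])
  # symmetric closure + self loops so receptors sharing a chain sequence match
  sym <- function(e, n_self) {
    data.table::data.table(
      i = c(e$i, e$j, seq_len(n_self)),
      j = c(e$j, e$i, seq_len(n_self)))
  }
  ae <- sym(ea, max(dt$aidx))
  be <- sym(eb, max(dt$bidx))
  data.table::setkey(be, i, j)
  cand <- merge(dt[, .(rid1 = rid, aidx, bidx1 = bidx)], ae,
                by.x = "aidx", by.y = "i", allow.cartesian = TRUE)
  cand <- merge(cand, dt[, .(rid2 = rid, aidx2 = aidx, bidx2 = bidx)],
                by.x = "j", by.y = "aidx2", allow.cartesian = TRUE)
  cand <- cand[rid1 < rid2]
  if (nrow(cand) == 0L)
    return(data.frame(rid1 = integer(), rid2 = integer()))
  keep <- !is.na(be[data.table::data.table(i = cand$bidx1, j = cand$bidx2),
                    on = c("i", "j"), which = TRUE])
  as.data.frame(unique(cand[keep, .(rid1, rid2)]))
}

# receptors joined iff d_alpha + d_beta <= budget
receptor_edges_sum <- function(rec, ea, eb, budget) {
  dt <- data.table::as.data.table(rec[, c("rid", "aidx", "bidx")])
  sym <- function(e, n_self) {
    data.table::data.table(
      i = c(e$i, e$j, seq_len(n_self)),
      j = c(e$j, e$i, seq_len(n_self)),
      d = c(e$d, e$d, rep(0, n_self)))
  }
  ae <- sym(ea, max(dt$aidx))
  be <- sym(eb, max(dt$bidx))
  data.table::setkey(be, i, j)
  cand <- merge(dt[, .(rid1 = rid, aidx, bidx1 = bidx)], ae,
                by.x = "aidx", by.y = "i", allow.cartesian = TRUE)
  cand <- merge(cand, dt[, .(rid2 = rid, aidx2 = aidx, bidx2 = bidx)],
                by.x = "j", by.y = "aidx2", allow.cartesian = TRUE)
  cand <- cand[rid1 < rid2]
  if (nrow(cand) == 0L)
    return(data.frame(rid1 = integer(), rid2 = integer()))
  bmatch <- be[data.table::data.table(i = cand$bidx1, j = cand$bidx2),
               on = c("i", "j")]
  keep <- !is.na(bmatch$d) & (cand$d + bmatch$d) <= budget
  as.data.frame(unique(cand[keep, .(rid1, rid2)]))
}

#' Clonotype size spectrum
#'
#' Frequency table of clonotype sizes, optionally restricted to the CD4 or
#' CD8 compartment (sizes are then recomputed within the compartment).
#'
#' @param assignment A `clonotype_assignment`.
#' @param compartment `"all"`, `"CD4"` or `"CD8"`; CD4 comprises the
#'   `Treg` and `CD4_*` phenotype labels, CD8 the `CD8_*` labels.
#' @return Tibble with `size`, `n_clonotypes`; attributes `min_size`,
#'   `max_size`.
#' @export
clonotype_size_spectrum <- function(assignment, compartment = c("all", "CD4", "CD8")) {
  compartment <- match.arg(compartment)
  cells <- assignment$cells
  if (compartment != "all") {
    if (!"phenotype" %in% names(cells))
      abort("phenotype labels required for compartment-restricted spectra")
    keep <- if (compartment == "CD4")
      cells$phenotype == "Treg" | startsWith(cells$phenotype, "CD4")
    else startsWith(cells$phenotype, "CD8")
    cells <- cells[keep, , drop = FALSE]
  }
  sizes <- as.integer(table(cells$clonotype_id))
  out <- as_tibble(as.data.frame(table(size = sizes), stringsAsFactors = FALSE))
  names(out) <- c("size", "n_clonotypes")
  out$size <- as.integer(out$size)
  attr(out, "min_size") <- min(sizes)
  attr(out, "max_size") <- max(sizes)
  out
}

#' Export the large-clonotype similarity network
#'
#' Nodes are clonotypes of at least `min_size` cells; edges join
#' "closely related" clonotypes — those whose representative receptors
#' are within `link_cutoff` on both chains. Because receptors within the
#' clonotype cutoff itself always end up in the same cluster, the link
#' threshold defaults to twice the clonotype cutoff.
#'
#' @param assignment A `clonotype_assignment`.
#' @param min_size Minimum clonotype size to include (default 15).
#' @param link_cutoff Distance threshold for between-clonotype edges;
#'   default `2 * params$cutoff`.
#' @param path Optional GraphML output path.
#' @return An igraph graph (invisibly if written to `path`).
#' @export
export_clonotype_network <- function(assignment, min_size = 15,
                                     link_cutoff = NULL, path = NULL) {
  link_cutoff <- link_cutoff %||% (2 * assignment$params$cutoff)
  cl <- assignment$clonotypes
  cl <- cl[cl$size >= min_size, , drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  if (nrow(cl) > 0L) {
    g <- igraph::make_empty_graph(n = nrow(cl), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = cl$clonotype_id)
    g <- igraph::set_vertex_attr(g, "size", value = cl$size)
    if ("private" %in% names(cl)) {
      g <- igraph::set_vertex_attr(g, "private", value = cl$private)
      g <- igraph::set_vertex_attr(g, "patients",
                                   value = vapply(cl$patients, paste,
                                                  collapse = ",", ""))
    }
    if (nrow(cl) > 1L) {
      params <- assignment$params
      ea <- distance_edges(cl$rep_alpha, params, cutoff = link_cutoff)
      eb <- distance_edges(cl$rep_beta, params, cutoff = link_cutoff)
      key <- function(e) paste(pmin(e$i, e$j), pmax(e$i, e$j))
      both <- intersect(key(ea), key(eb))
      if (length(both)) {
        ij <- do.call(rbind, strsplit(both, " "))
        g <- igraph::add_edges(g, rbind(as.integer(ij[, 1]), as.integer(ij[, 2])))
      }
    }
  }
  if (!is.null(path)) {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(g))
  }
  g
}
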