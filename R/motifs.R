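# GLIPH-style specificity-group clustering of CDR3beta sequences: global
# edges between near-identical CDR3s differing by one exchangeable
# substitution, local edges between CDR3s sharing an enriched k-mer motif,
# and connected components of the union as putative specificity groups.

#' Trim conserved CDR3 flanks for motif mining
#'
#' Removes `n_term` N-terminal and `c_term` C-terminal residues (the
#' conserved C...F/W framework) so k-mer mining sees only the
#' antigen-contact loop interior. Sequences too short to retain any
#' interior return `NA` and are excluded (logged).
#'
#' @param cdr3 Character vector of CDR3 amino-acid sequences.
#' @param n_term,c_term Residues to trim from each end (default 3).
#' @return Character vector of interiors (`NA` where too short).
#' @export
#' @examples
#' trim_cdr3("CASSLGETQYF") # "SLGET"
trim_cdr3 <- function(cdr3, n_term = 3, c_term = 3) {
  len <- nchar(cdr3)
  out <- ifelse(len > n_term + c_term,
                substr(cdr3, n_term + 1L, len - c_term), NA_character_)
  n_bad <- sum(is.na(out))
  if (n_bad) ct_log("trim_cdr3: %d sequence(s) too short for motif mining", n_bad)
  out
}

#' Global similarity edges between CDR3 sequences
#'
#' Connects CDR3s of equal length that are identical or differ at exactly
#' one position where the substituted pair is exchangeable under BLOSUM62
#' (substitution score >= `exchange_threshold`).
#'
#' @param cdr3 Character vector of CDR3 sequences (full length, untrimmed).
#' @param exchange_threshold Minimum BLOSUM62 score of the differing pair
#'   (default 1, i.e. strictly positive).
#' @return Tibble of undirected edges (`a`, `b` as indices into `cdr3`,
#'   `type = "global"`).
#' @export
global_similarity_edges <- function(cdr3, exchange_threshold = 1) {
  n <- length(cdr3)
  if (n < 2L) return(tibble(a = integer(), b = integer(), type = character()))
  bl <- blosum62()
  out_a <- integer(0); out_b <- integer(0)
  for (len in unique(nchar(cdr3))) {
    idx <- which(nchar(cdr3) == len)
    if (length(idx) < 2L) next
    chars <- do.call(rbind, strsplit(cdr3[idx], ""))
    for (u in seq_len(length(idx) - 1L)) {
      for (v in seq.int(u + 1L, length(idx))) {
        diff <- which(chars[u, ] != chars[v, ])
        ok <- length(diff) == 0L ||
          (length(diff) == 1L &&
             bl[chars[u, diff], chars[v, diff]] >= exchange_threshold)
        if (ok) { out_a <- c(out_a, idx[u]); out_b <- c(out_b, idx[v]) }
      }
    }
  }
  tibble(a = out_a, b = out_b, type = rep("global", length(out_a)))
}

# presence/absence k-mer counts over trimmed interiors of unique CDR3s
kmer_presence <- function(interiors, k) {
  interiors <- interiors[!is.na(interiors) & nchar(interiors) >= k]
  if (!length(interiors)) return(integer(0))
  kmers <- unlist(lapply(interiors, function(s) {
    n <- nchar(s)
    unique(substring(s, 1:(n - k + 1), k:n))
  }))
  table(kmers)
}

#' Mine locally enriched CDR3 k-mer motifs
#'
#' Counts each k-mer's presence (once per unique CDR3 interior) in the
#' query and in a background repertoire, tests enrichment with a
#' one-sided hypergeometric (Fisher 2 x 2) test and keeps motifs passing
#' the count, fold-enrichment and p-value thresholds.
#'
#' @param cdr3 Query CDR3 sequences (full length; trimmed internally).
#' @param background Background CDR3 sequences; defaults to a naive
#'   repertoire of 5000 sequences drawn from the package's CDR3 model
#'   with a fixed seed (see [simulate_naive_cdr3()]).
#' @param k_set Motif lengths to mine (default 3 and 4).
#' @param min_count Minimum query CDR3s containing the motif (default 3).
#' @param p_max Enrichment p-value ceiling (default 1e-3).
#' @param fold_min Minimum fold enrichment over background (default 10;
#'   background counts of zero use a 0.5 pseudocount for the fold only).
#' @return Tibble of motif hits: `motif`, `k`, `n_query`, `n_background`,
#'   `fold`, `p`.
#' @export
mine_local_motifs <- function(cdr3, background = NULL, k_set = c(3, 4),
                              min_count = 3, p_max = 1e-3, fold_min = 10) {
  if (is.null(background))
    background <- with_seed(104729L, simulate_naive_cdr3(5000))
  q_int <- unique(trim_cdr3(unique(cdr3)))
  b_int <- unique(trim_cdr3(unique(background)))
  q_int <- q_int[!is.na(q_int)]; b_int <- b_int[!is.na(b_int)]
  if (!length(q_int)) abort("no query CDR3 long enough for motif mining")
  if (length(b_int) < length(q_int))
    warn("background repertoire smaller than query; enrichment will be unstable")
  hits <- list()
  for (k in k_set) {
    qt <- kmer_presence(q_int, k)
    qt <- qt[qt >= min_count]
    if (!length(qt)) next
    bt <- kmer_presence(b_int, k)
    nq <- sum(nchar(q_int) >= k); nb <- sum(nchar(b_int) >= k)
    bcount <- as.integer(bt[names(qt)]); bcount[is.na(bcount)] <- 0L
    qcount <- as.integer(qt)
    # one-sided hypergeometric upper tail on (motif+/-) x (query/background)
    p <- phyper(qcount - 1L, qcount + bcount, nq + nb - qcount - bcount,
                nq, lower.tail = FALSE)
    fold <- (qcount / nq) / (pmax(bcount, 0.5) / nb)
    keep <- p <= p_max & fold >= fold_min
    if (any(keep))
      hits[[as.character(k)]] <- tibble(
        motif = names(qt)[keep], k = k, n_query = qcount[keep],
        n_background = bcount[keep], fold = fold[keep], p = p[keep])
  }
  if (!length(hits))
    return(tibble(motif = character(), k = integer(), n_query = integer(),
                  n_background = integer(), fold = numeric(), p = numeric()))
  dplyr::arrange(dplyr::bind_rows(hits), .data$p, .data$motif)
}

#' Local similarity edges from shared enriched motifs
#'
#' Connects two CDR3s that share an enriched motif whose start positions
#' in the trimmed interiors (0-based) differ by at most `max_shift`.
#'
#' @param cdr3 Query CDR3 sequences (full length).
#' @param hits Motif hits from [mine_local_motifs()].
#' @param max_shift Maximum allowed motif-position shift (default 3).
#' @return Tibble of undirected edges (`a`, `b`, `type = "local"`,
#'   `motif`).
#' @export
local_similarity_edges <- function(cdr3, hits, max_shift = 3) {
  empty <- tibble(a = integer(), b = integer(), type = character(),
                  motif = character())
  if (nrow(hits) == 0L) return(empty)
  interiors <- trim_cdr3(cdr3)
  out <- list()
  for (m in hits$motif) {
    pos <- lapply(interiors, function(s) {
      if (is.na(s)) return(integer(0))
      g <- gregexpr(m, s, fixed = TRUE)[[1]]
      if (g[1] == -1L) integer(0) else as.integer(g) - 1L
    })
    members <- which(lengths(pos) > 0)
    if (length(members) < 2L) next
    for (u in seq_len(length(members) - 1L)) {
      for (v in seq.int(u + 1L, length(members))) {
        pu <- pos[[members[u]]]; pv <- pos[[members[v]]]
        if (min(abs(outer(pu, pv, "-"))) <= max_shift)
          out[[length(out) + 1L]] <- tibble(
            a = members[u], b = members[v], type = "local", motif = m)
      }
    }
  }
  if (!length(out)) return(empty)
  dplyr::distinct(dplyr::bind_rows(out))
}

#' Build motif clusters from global and local edges
#'
#' Connected components of the union of global and local similarity
#' edges over unique CDR3s; singletons are never clusters, and only
#' components with at least `min_report_size` members are reported.
#'
#' @param entries Tibble with columns `cdr3_aa` and `dataset_label`
#'   (rows with the same CDR3 under different labels are allowed).
#' @param min_report_size Minimum member count to report (presets used in
#'   practice: 3, 10, 20; default 3).
#' @param background,exchange_threshold,k_set,min_count,p_max,fold_min,max_shift
#'   Passed to the edge-construction stages.
#' @return A list of class `motif_clusters`: `clusters` (tibble
#'   `cluster_id`, `cdr3_aa`, `dataset_label`, `cluster_size`), `edges`
#'   (typed edge list over unique CDR3s), `hits` (motif table) and
#'   `n_unique` (unique CDR3 count).
#' @export
build_motif_clusters <- function(entries, min_report_size = 3,
                                 background = NULL, exchange_threshold = 1,
                                 k_set = c(3, 4), min_count = 3,
                                 p_max = 1e-3, fold_min = 10, max_shift = 3) {
  if (!is.data.frame(entries) || !all(c("cdr3_aa", "dataset_label") %in% names(entries)))
    abort("entries must have columns cdr3_aa and dataset_label")
  uniq <- sort(unique(entries$cdr3_aa))
  ge <- global_similarity_edges(uniq, exchange_threshold)
  hits <- mine_local_motifs(uniq, background = background, k_set = k_set,
                            min_count = min_count, p_max = p_max,
                            fold_min = fold_min)
  le <- local_similarity_edges(uniq, hits, max_shift = max_shift)
  edges <- dplyr::bind_rows(ge, le)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$a, to = edges$b),
    directed = FALSE, vertices = data.frame(name = seq_along(uniq)))
  comp <- igraph::components(g)$membership[as.character(seq_along(uniq))]
  sizes <- table(comp)
  keep <- names(sizes)[sizes >= max(2L, min_report_size)]
  # deterministic ids: by descending size then smallest member CDR3
  ord <- order(-as.integer(sizes[keep]),
               vapply(keep, function(k) min(uniq[comp == k]), ""))
  keep <- keep[ord]
  cl_id <- setNames(make_ids("mc", length(keep)), keep)
  members <- tibble(cdr3_aa = uniq, comp = as.character(comp)) |>
    dplyr::filter(.data$comp %in% keep) |>
    dplyr::mutate(cluster_id = unname(cl_id[.data$comp]))
  clusters <- entries |>
    dplyr::distinct(.data$cdr3_aa, .data$dataset_label) |>
    dplyr::inner_join(members[, c("cdr3_aa", "cluster_id")], by = "cdr3_aa")
  csize <- members |> dplyr::count(.data$cluster_id, name = "cluster_size")
  clusters$cluster_size <- csize$cluster_size[match(clusters$cluster_id, csize$cluster_id)]
  clusters <- dplyr::arrange(clusters, .data$cluster_id, .data$cdr3_aa)
  edges$cdr3_a <- uniq[edges$a]
  edges$cdr3_b <- uniq[edges$b]
  structure(list(clusters = clusters, edges = edges, hits = hits,
                 n_unique = length(uniq)),
            class = "motif_clusters")
}

#' Fraction of clustered query CDR3s co-clustering with reference CDR3s
#'
#' Among query-label CDR3s that belong to any reported cluster, the
#' fraction whose cluster also contains at least one CDR3 carrying one of
#' the reference labels. Counts unique CDR3s.
#'
#' @param clusters A `motif_clusters` object.
#' @param query_label Dataset label of the query set.
#' @param reference_labels Character vector of reference labels.
#' @return Fraction in \[0, 1\], or `NA` (with a warning) when no query
#'   CDR3 is clustered.
#' @export
cross_dataset_fraction <- function(clusters, query_label, reference_labels) {
  cl <- clusters$clusters
  q <- unique(cl$cdr3_aa[cl$dataset_label == query_label])
  if (!length(q)) {
    warn("no clustered query CDR3s; cross-dataset fraction undefined")
    return(NA_real_)
  }
  ref_clusters <- unique(cl$cluster_id[cl$dataset_label %in% reference_labels])
  q_clusters <- cl[cl$dataset_label == query_label, c("cdr3_aa", "cluster_id")]
  hit <- tapply(q_clusters$cluster_id %in% ref_clusters, q_clusters$cdr3_aa, any)
  mean(hit)
}

#' Position frequency matrix of CDR3 sequences
#'
#' Per-column amino-acid frequencies for sequence-logo plotting, either
#' stratified by CDR3 length or center-padded to a common width (gap
#' characters inserted at the midpoint and excluded from normalization).
#'
#' @param cdr3 Character vector of CDR3 sequences.
#' @param scheme `"length-stratified"` (default) or `"center-pad"`.
#' @return For length-stratified: a named list of 20 x L matrices (one
#'   per observed length). For center-pad: a single 20 x W matrix, W the
#'   maximum length. Columns sum to 1 (over non-gap residues).
#' @export
position_frequency_matrix <- function(cdr3, scheme = c("length-stratified", "center-pad")) {
  scheme <- match.arg(scheme)
  if (!length(cdr3)) abort("no sequences supplied")
  pfm_of <- function(mat) {
    apply(mat, 2, function(col) {
      col <- col[col != "-"]
      tab <- table(factor(col, levels = AA20))
      as.numeric(tab) / length(col)
    })
  }
  if (scheme == "length-stratified") {
    out <- list()
    for (len in sort(unique(nchar(cdr3)))) {
      mat <- do.call(rbind, strsplit(cdr3[nchar(cdr3) == len], ""))
      m <- pfm_of(mat)
      rownames(m) <- AA20
      out[[as.character(len)]] <- m
    }
    out
  } else {
    w <- max(nchar(cdr3))
    padded <- vapply(cdr3, function(s) {
      n <- nchar(s)
      half <- ceiling(n / 2)
      paste0(substr(s, 1, half), strrep("-", w - n), substr(s, half + 1, n))
    }, "", USE.NAMES = FALSE)
    mat <- do.call(rbind, strsplit(padded, ""))
    m <- pfm_of(mat)
    rownames(m) <- AA20
    m
  }
}
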