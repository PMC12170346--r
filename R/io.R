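# Readers/writers for TCR chain tables (AIRR Rearrangement TSV, 10x
# filtered-contig CSV) and the cell metadata table. All loaders return the
# package's internal chain layout:
#   cell_id, locus, cdr3_aa, cdr3_nt, v_gene, j_gene, productive, umis

CHAIN_COLS <- c("cell_id", "locus", "cdr3_aa", "cdr3_nt",
                "v_gene", "j_gene", "productive", "umis")

ARM_LEVELS <- c("placebo", "IL2_1.5", "IL2_2.5")
TIMEPOINT_LEVELS <- c("pre", "post")

#' Default phenotype label set
#'
#' Eight T cell populations used throughout: regulatory T cells plus CD4
#' and CD8 naive/memory subsets.
#' @return Character vector of labels.
#' @export
default_phenotypes <- function() {
  c("Treg", "CD4_naive", "CD4_Tcm", "CD4_Tem",
    "CD8_naive", "CD8_Tcm", "CD8_Tem", "CD8_Temra")
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("t", "true", "1", "yes")
}

normalise_locus <- function(x) {
  x <- toupper(as.character(x))
  out <- ifelse(x == "TRA", "TRA", ifelse(x == "TRB", "TRB", "other"))
  out
}

#' Read an AIRR Rearrangement TSV of TCR chains
#'
#' Requires the AIRR columns `cell_id`, `locus`, `junction_aa`, `v_call`,
#' `j_call`, `productive`; `junction` (nucleotide) and `duplicate_count`
#' are used when present. Non-TRA/TRB rows are retained with
#' `locus = "other"` so the QC stage can account for them.
#'
#' @param path Path to a tab-separated AIRR Rearrangement file.
#' @return Tibble of chain records.
#' @export
read_airr <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cell_id", "locus", "junction_aa", "v_call", "j_call", "productive")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(sprintf("AIRR file is missing mandatory column(s): %s",
                  paste(miss, collapse = ", ")))
  tibble(
    cell_id = as.character(df$cell_id),
    locus = normalise_locus(df$locus),
    cdr3_aa = as.character(df$junction_aa),
    cdr3_nt = if ("junction" %in% names(df)) as.character(df$junction) else NA_character_,
    v_gene = as.character(df$v_call),
    j_gene = as.character(df$j_call),
    productive = parse_logical(df$productive),
    umis = if ("duplicate_count" %in% names(df)) as.integer(df$duplicate_count) else NA_integer_
  )
}

#' Write chain records as an AIRR Rearrangement TSV
#'
#' @param chains Chain tibble in the internal layout (see [read_airr()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(chains, path) {
  out <- tibble(
    cell_id = chains$cell_id,
    locus = chains$locus,
    junction_aa = chains$cdr3_aa,
    junction = chains$cdr3_nt,
    v_call = chains$v_gene,
    j_call = chains$j_gene,
    productive = ifelse(chains$productive, "T", "F"),
    duplicate_count = chains$umis
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a 10x filtered-contig annotation CSV
#'
#' Column dialect: `barcode`, `chain`, `cdr3`, `cdr3_nt`, `v_gene`,
#' `j_gene`, `productive`, `umis`.
#'
#' @param path Path to a comma-separated contig annotation file.
#' @return Tibble of chain records (internal layout).
#' @export
read_10x_contigs <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("barcode", "chain", "cdr3", "v_gene", "j_gene", "productive")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(sprintf("10x contig file is missing mandatory column(s): %s",
                  paste(miss, collapse = ", ")))
  tibble(
    cell_id = as.character(df$barcode),
    locus = normalise_locus(df$chain),
    cdr3_aa = as.character(df$cdr3),
    cdr3_nt = if ("cdr3_nt" %in% names(df)) as.character(df$cdr3_nt) else NA_character_,
    v_gene = as.character(df$v_gene),
    j_gene = as.character(df$j_gene),
    productive = parse_logical(df$productive),
    umis = if ("umis" %in% names(df)) as.integer(df$umis) else NA_integer_
  )
}

#' Write chain records in the 10x contig CSV dialect
#' @inheritParams write_airr
#' @export
write_10x_contigs <- function(chains, path) {
  out <- tibble(
    barcode = chains$cell_id,
    chain = chains$locus,
    cdr3 = chains$cdr3_aa,
    cdr3_nt = chains$cdr3_nt,
    v_gene = chains$v_gene,
    j_gene = chains$j_gene,
    productive = ifelse(chains$productive, "true", "false"),
    umis = chains$umis
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read the cell metadata table
#'
#' Tab-separated with columns `cell_id`, `patient_id`, `timepoint`
#' (pre/post), `arm` (placebo, IL2_1.5, IL2_2.5) and `phenotype`.
#'
#' @param path Path to the metadata TSV.
#' @param phenotypes Allowed phenotype label set.
#' @return Tibble of cell metadata.
#' @export
read_cell_meta <- function(path, phenotypes = default_phenotypes()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cell_id", "patient_id", "timepoint", "arm", "phenotype")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(sprintf("metadata is missing column(s): %s", paste(miss, collapse = ", ")))
  validate_cell_meta(as_tibble(df[need]), phenotypes)
}

validate_cell_meta <- function(meta, phenotypes = default_phenotypes()) {
  if (!all(meta$timepoint %in% TIMEPOINT_LEVELS))
    abort("timepoint must be 'pre' or 'post'")
  if (!all(meta$arm %in% ARM_LEVELS))
    abort(sprintf("arm must be one of: %s", paste(ARM_LEVELS, collapse = ", ")))
  bad <- setdiff(unique(meta$phenotype), phenotypes)
  if (length(bad))
    abort(sprintf("unknown phenotype label(s): %s", paste(bad, collapse = ", ")))
  if (anyDuplicated(meta$cell_id))
    abort("cell_id values must be unique across samples")
  meta
}

#' Write cell metadata
#' @param meta Metadata tibble.
#' @param path Output path (TSV).
#' @export
write_cell_meta <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}
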