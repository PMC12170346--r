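# Internal helpers shared across modules.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Validate an amino-acid sequence over the 20-letter alphabet
#' @noRd
check_aa <- function(x, arg = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    abort(sprintf("%s must be a non-empty amino-acid string", arg))
  res <- strsplit(x, "")[[1]]
  bad <- which(!res %in% AA20)
  if (length(bad))
    abort(sprintf("invalid residue '%s' at position %d of %s", res[bad[1]], bad[1], arg))
  invisible(x)
}

#' Run an expression with a temporary RNG seed, restoring RNG state
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# INFO-level logging, off unless options(clonotrack.verbose = TRUE)
ct_log <- function(fmt, ...) {
  if (isTRUE(getOption("clonotrack.verbose", FALSE)))
    inform(sprintf(fmt, ...))
  invisible(NULL)
}

# stable sprintf-style id maker: ct00001, mc003, ...
make_ids <- function(prefix, n) sprintf("%s%0*d", prefix, max(3L, nchar(n)), seq_len(n))
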