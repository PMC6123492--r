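#' Normalize an RNA sequence string
#'
#' Upper-cases, converts DNA-style \code{T} to \code{U}, and validates the
#' alphabet against \code{\{A, C, G, U\}}.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages (e.g. \code{"read"}).
#' @return character vector of normalized RNA sequences.
#' @export
normalize_rna <- function(x, what = "sequence") {
  if (!is.character(x)) stop(what, " must be a character vector")
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    stop("non-RNA characters in ", what, ": ",
         paste(utils::head(x[bad], 3L), collapse = ", "))
  }
  out
}

# longest common prefix length of two strings
lcp_length <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  diff <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(diff) == 0L) n else diff[1L] - 1L
}

#' Derive a stage seed from a global seed
#'
#' A fixed integer derivation so that pipeline stages are independently
#' reproducible from one global seed.
#'
#' @param seed global integer seed.
#' @param stage integer stage index (>= 1).
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(stage), length(stage) == 1L, stage >= 1)
  as.integer((abs(seed) + 1000003 * stage) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
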