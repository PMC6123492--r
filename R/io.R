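#' Read a FASTA file of RNA sequences
#'
#' Order-preserving reader; sequences are normalized to RNA (upper case,
#' \code{T} read as \code{U}). Duplicate record ids are an error.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns \code{id}, \code{sequence}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- names(set)
  if (any(Biostrings::width(set) == 0L)) {
    stop("header-only FASTA record(s) without sequence: ",
         paste(utils::head(ids[Biostrings::width(set) == 0L], 3L),
               collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(id = ids,
             sequence = normalize_rna(as.character(set), what = path),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param ids record identifiers.
#' @param sequences character vector of sequences.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  set <- Biostrings::BStringSet(sequences)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Read small-RNA reads with counts
#'
#' Accepts FASTA (counts encoded in headers as \code{>name_xCOUNT}, default 1
#' when absent), FASTQ (each record counts once), or a two-column TSV
#' (\code{sequence}, \code{count}). Format is inferred from the file extension
#' unless given.
#'
#' @param path input file.
#' @param format one of \code{"auto"}, \code{"fasta"}, \code{"fastq"},
#'   \code{"tsv"}.
#' @return data.frame with columns \code{sequence}, \code{count}.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     fa = , fasta = , fna = "fasta",
                     fq = , fastq = "fastq",
                     tsv = , txt = , tab = "tsv",
                     stop("cannot infer read format from extension: ", ext))
  }
  if (format == "tsv") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("sequence", "count"),
                             colClasses = c("character", "numeric"))
    if (any(is.na(tab$count)) || any(tab$count < 0)) {
      stop("counts must be non-negative numbers in ", path)
    }
    tab$sequence <- normalize_rna(tab$sequence, what = path)
    return(tab)
  }
  set <- Biostrings::readBStringSet(path, format = format)
  counts <- rep(1, length(set))
  if (format == "fasta") {
    m <- regmatches(names(set), regexec("_x([0-9]+)$", names(set)))
    hit <- lengths(m) == 2L
    counts[hit] <- as.numeric(vapply(m[hit], `[`, character(1L), 2L))
  }
  data.frame(sequence = normalize_rna(as.character(set), what = path),
             count = counts, stringsAsFactors = FALSE)
}

#' Write a data frame as TSV
#'
#' Tab-separated, UTF-8, header row, no quoting or row names: the package's
#' universal tabular output format.
#'
#' @param x data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a backbone amide chemical shift table
#'
#' Three-column TSV per spectrum: residue number, 1H shift (ppm), 15N shift
#' (ppm); an optional fourth column holds the amino-acid code. Missing rows
#' mean the cross-peak was not observed.
#'
#' @param path path to the TSV (with header).
#' @return data.frame with columns \code{residue}, \code{dH}, \code{dN} and
#'   optionally \code{aa}.
#' @export
read_shift_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("residue", "dH", "dN")
  if (!all(need %in% names(tab))) {
    stop("shift table must have columns residue, dH, dN: ", path)
  }
  if (anyDuplicated(tab$residue)) stop("duplicate residue numbers in ", path)
  if (any(!is.finite(tab$dH)) || any(!is.finite(tab$dN))) {
    stop("non-finite chemical shifts in ", path)
  }
  tab
}
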