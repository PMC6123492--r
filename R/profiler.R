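#' Build a mature miRNA reference set
#'
#' A reference set holds named mature small-RNA sequences against which reads
#' are classified. Sequences are normalized to RNA; ids must be unique and
#' every reference must be at least 15 nt (shorter sequences cannot anchor a
#' 5'-matched assignment reliably).
#'
#' @param id character vector of unique miRNA identifiers.
#' @param sequence character vector of mature sequences (5'->3').
#' @param methylated_3p logical, whether the 3'-terminal ribose carries a
#'   2'-O-methyl group (HEN1-type protection). Recycled.
#' @return a \code{mirna_refs} data.frame with columns \code{id},
#'   \code{sequence}, \code{length}, \code{methylated_3p}.
#' @export
mirna_references <- function(id, sequence, methylated_3p = TRUE) {
  stopifnot(length(id) == length(sequence), length(id) >= 1L)
  if (anyDuplicated(id)) {
    stop("reference ids must be unique: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sequence <- normalize_rna(sequence, what = "reference sequence")
  L <- nchar(sequence)
  if (any(L < 15L)) {
    stop("reference sequences must be >= 15 nt; offending: ",
         paste(id[L < 15L], collapse = ", "))
  }
  refs <- data.frame(id = as.character(id), sequence = sequence, length = L,
                     methylated_3p = rep_len(as.logical(methylated_3p),
                                             length(id)),
                     stringsAsFactors = FALSE)
  class(refs) <- c("mirna_refs", "data.frame")
  refs
}

#' Read mature miRNA references from FASTA
#'
#' @param path FASTA file of mature miRNA sequences.
#' @param methylated_3p logical flag applied to all records.
#' @return a \code{mirna_refs} object (see [mirna_references()]).
#' @export
read_references <- function(path, methylated_3p = TRUE) {
  fa <- read_fasta(path)
  mirna_references(fa$id, fa$sequence, methylated_3p)
}

read_category <- function(t, m) {
  if (t == 0L && m == 0L) "FL"
  else if (t > 0L && m == 0L) "TR"
  else if (t == 0L && m > 0L) "TA"
  else "TR+TA"
}

#' Classify one read against a reference set
#'
#' 5'-anchored prefix classification: for each reference the longest prefix
#' length q with \code{read[1:q] == reference[1:q]} is found; the candidate
#' assignment is truncation \code{t = L - q} with tail \code{read[(q+1):]}.
#' A candidate is valid iff \code{q >= q_min}, \code{t <= t_max} and tail
#' length \code{m <= m_max}. The winner maximizes q, then minimizes t, then
#' takes the lexicographically smallest reference id. Ambiguous tail
#' nucleotides (a tail base equal to the next templated base) are absorbed
#' into the reference prefix, minimizing apparent truncation; the convention
#' is deterministic.
#'
#' @param read RNA string (case-insensitive; \code{T} read as \code{U}).
#' @param refs a \code{mirna_refs} object.
#' @param q_min minimum matched prefix (nt) for an assignment.
#' @param t_max maximum truncation (nt).
#' @param m_max maximum tail length (nt).
#' @return one-row data.frame: \code{read_sequence}, \code{mirna_id} (NA when
#'   unassigned), \code{t}, \code{tail}, \code{m}, \code{category}.
#' @export
classify_read <- function(read, refs, q_min = 12L, t_max = 8L, m_max = 8L) {
  if (!inherits(refs, "mirna_refs") || nrow(refs) == 0L) {
    stop("refs must be a non-empty mirna_refs reference set")
  }
  read <- normalize_rna(read, what = "read")
  stopifnot(length(read) == 1L, nchar(read) > 0L)
  best <- NULL
  for (i in seq_len(nrow(refs))) {
    L <- refs$length[i]
    q <- lcp_length(read, refs$sequence[i])
    t <- L - q
    m <- nchar(read) - q
    if (q < q_min || t > t_max || m > m_max) next
    cand <- list(q = q, t = t, m = m, id = refs$id[i])
    if (is.null(best) ||
        cand$q > best$q ||
        (cand$q == best$q && cand$t < best$t) ||
        (cand$q == best$q && cand$t == best$t && cand$id < best$id)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    return(data.frame(read_sequence = read, mirna_id = NA_character_,
                      t = NA_integer_, tail = NA_character_, m = NA_integer_,
                      category = "UNASSIGNED", stringsAsFactors = FALSE))
  }
  tail <- substr(read, best$q + 1L, nchar(read))
  data.frame(read_sequence = read, mirna_id = best$id,
             t = as.integer(best$t), tail = tail, m = as.integer(best$m),
             category = read_category(best$t, best$m),
             stringsAsFactors = FALSE)
}

#' Build a truncation/tailing profile from a read set
#'
#' Identical sequences are merged (counts summed) before classification;
#' every input count lands exactly once in the assigned or unassigned tally,
#' so read counts are conserved.
#'
#' @param reads data.frame with columns \code{sequence} and \code{count}
#'   (counts >= 0), e.g. from [read_reads()].
#' @param refs a \code{mirna_refs} object.
#' @param q_min,t_max,m_max classification parameters, see [classify_read()].
#' @return a \code{trim_profile} object: list with \code{assignments}
#'   (data.frame mirna_id, t, tail, m, count aggregated over species),
#'   \code{reads} (per-sequence classification), \code{assigned},
#'   \code{unassigned}, \code{total}, \code{ref_ids}, \code{params}.
#' @export
build_profile <- function(reads, refs, q_min = 12L, t_max = 8L, m_max = 8L) {
  stopifnot(is.data.frame(reads), all(c("sequence", "count") %in% names(reads)))
  if (any(reads$count < 0)) stop("read counts must be non-negative")
  params <- list(q_min = q_min, t_max = t_max, m_max = m_max)
  if (nrow(reads) == 0L) {
    prof <- list(assignments = data.frame(mirna_id = character(),
                                          t = integer(), tail = character(),
                                          m = integer(), count = numeric(),
                                          stringsAsFactors = FALSE),
                 reads = data.frame(), assigned = 0, unassigned = 0, total = 0,
                 ref_ids = refs$id, params = params)
    class(prof) <- "trim_profile"
    return(prof)
  }
  seqs <- normalize_rna(reads$sequence, what = "reads")
  merged <- stats::aggregate(list(count = reads$count),
                             by = list(sequence = seqs), FUN = sum)
  cls <- do.call(rbind, lapply(merged$sequence, classify_read, refs = refs,
                               q_min = q_min, t_max = t_max, m_max = m_max))
  cls$count <- merged$count
  hit <- !is.na(cls$mirna_id)
  assigned <- cls[hit, , drop = FALSE]
  if (nrow(assigned) > 0L) {
    agg <- stats::aggregate(list(count = assigned$count),
                            by = list(mirna_id = assigned$mirna_id,
                                      t = assigned$t, tail = assigned$tail),
                            FUN = sum)
    agg$m <- nchar(agg$tail)
    agg <- agg[order(agg$mirna_id, agg$t, agg$m, agg$tail),
               c("mirna_id", "t", "tail", "m", "count")]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(mirna_id = character(), t = integer(),
                      tail = character(), m = integer(), count = numeric(),
                      stringsAsFactors = FALSE)
  }
  prof <- list(assignments = agg, reads = cls,
               assigned = sum(assigned$count),
               unassigned = sum(cls$count[!hit]),
               total = sum(cls$count), ref_ids = refs$id, params = params)
  class(prof) <- "trim_profile"
  prof
}

#' @export
print.trim_profile <- function(x, ...) {
  cat("trim_profile:", length(unique(x$assignments$mirna_id)),
      "miRNAs,", x$assigned, "assigned /", x$total, "total counts\n")
  invisible(x)
}

profile_counts <- function(profile, mirna_id) {
  if (!mirna_id %in% profile$ref_ids) {
    stop("unknown miRNA id: ", mirna_id)
  }
  profile$assignments[profile$assignments$mirna_id == mirna_id, , drop = FALSE]
}

#' Truncated-to-full-length ratio (TR/FL)
#'
#' The trimming-activity statistic: counts of 3'-truncated species divided by
#' full-length species for one miRNA. By default tailed species are excluded
#' from both terms (\code{FL = count(t = 0, m = 0)},
#' \code{TR = sum over t >= 1 of count(t, m = 0)}); with
#' \code{include_tailed = TRUE} tails are ignored, i.e. both terms sum over
#' all tail lengths.
#'
#' @param profile a \code{trim_profile}.
#' @param mirna_id reference id present in the profile's reference set.
#' @param include_tailed logical, see above.
#' @return numeric ratio; \code{Inf} when FL = 0 with TR > 0 (flagged via
#'   attribute \code{flagged}), \code{NA} when FL = TR = 0.
#' @export
tr_fl_ratio <- function(profile, mirna_id, include_tailed = FALSE) {
  cts <- profile_counts(profile, mirna_id)
  if (!include_tailed) cts <- cts[cts$m == 0L, , drop = FALSE]
  fl <- sum(cts$count[cts$t == 0L])
  tr <- sum(cts$count[cts$t >= 1L])
  if (fl == 0 && tr == 0) return(NA_real_)
  if (fl == 0) {
    out <- Inf
    attr(out, "flagged") <- TRUE
    return(out)
  }
  tr / fl
}

#' TR/FL ratios for every miRNA in a profile
#'
#' @inheritParams tr_fl_ratio
#' @return data.frame: \code{mirna_id}, \code{fl}, \code{tr}, \code{ratio}.
#' @export
tr_fl_table <- function(profile, include_tailed = FALSE) {
  ids <- profile$ref_ids
  cts <- profile$assignments
  if (!include_tailed) cts <- cts[cts$m == 0L, , drop = FALSE]
  fl <- vapply(ids, function(id)
    sum(cts$count[cts$mirna_id == id & cts$t == 0L]), numeric(1L))
  tr <- vapply(ids, function(id)
    sum(cts$count[cts$mirna_id == id & cts$t >= 1L]), numeric(1L))
  ratio <- ifelse(fl == 0 & tr == 0, NA_real_,
                  ifelse(fl == 0, Inf, tr / fl))
  data.frame(mirna_id = ids, fl = fl, tr = tr, ratio = ratio,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Truncation-by-tailing proportion matrix
#'
#' Per-miRNA matrix over truncation t = 0..t_max (rows) and tail length
#' m = 0..m_max (columns) of species proportions (counts divided by the
#' miRNA's assigned total). Species beyond a cap accumulate into the cap bin
#' and the matrix is flagged (\code{attr(, "capped")}).
#'
#' @param profile a \code{trim_profile}.
#' @param mirna_id reference id.
#' @param t_max,m_max axis caps; default to the profile's own parameters.
#' @return numeric matrix; proportions sum to 1 when the miRNA has assigned
#'   reads. With zero assigned reads an all-\code{NA} matrix with attribute
#'   \code{empty = TRUE} is returned (no division by zero).
#' @export
truncation_tailing_matrix <- function(profile, mirna_id,
                                      t_max = profile$params$t_max,
                                      m_max = profile$params$m_max) {
  cts <- profile_counts(profile, mirna_id)
  mat <- matrix(0, nrow = t_max + 1L, ncol = m_max + 1L,
                dimnames = list(t = 0:t_max, m = 0:m_max))
  if (nrow(cts) == 0L || sum(cts$count) == 0) {
    mat[] <- NA_real_
    attr(mat, "empty") <- TRUE
    return(mat)
  }
  capped <- FALSE
  for (i in seq_len(nrow(cts))) {
    t <- cts$t[i]; m <- cts$m[i]
    if (t > t_max || m > m_max) capped <- TRUE
    mat[min(t, t_max) + 1L, min(m, m_max) + 1L] <-
      mat[min(t, t_max) + 1L, min(m, m_max) + 1L] + cts$count[i]
  }
  mat <- mat / sum(cts$count)
  attr(mat, "capped") <- capped
  mat
}

#' Long-format export of a truncation/tailing matrix
#'
#' @param mat matrix from [truncation_tailing_matrix()].
#' @param mirna_id id to stamp on rows.
#' @return data.frame \code{mirna_id}, \code{t}, \code{m}, \code{proportion}.
#' @export
matrix_to_long <- function(mat, mirna_id) {
  grid <- expand.grid(t = as.integer(rownames(mat)),
                      m = as.integer(colnames(mat)))
  data.frame(mirna_id = mirna_id, t = grid$t, m = grid$m,
             proportion = as.vector(mat), stringsAsFactors = FALSE)
}

#' Compare TR/FL ratios between two conditions
#'
#' Per-miRNA comparison of two profiles built against the same reference set
#' (e.g. a catalytic-dead control vs an active enzyme). miRNAs with FL counts
#' below \code{min_fl} in either condition are excluded as under-evidenced.
#' A miRNA is flagged as trimmed in condition B when
#' \code{ratio_b > fold_threshold * ratio_a}.
#'
#' @param profile_a,profile_b \code{trim_profile} objects (A = control).
#' @param min_fl minimum full-length count required in both conditions.
#' @param fold_threshold flagging multiplier (default 2).
#' @param include_tailed passed to [tr_fl_table()].
#' @return data.frame: \code{mirna_id}, \code{fl_a}, \code{fl_b},
#'   \code{ratio_a}, \code{ratio_b}, \code{log2_fc}, \code{flagged}.
#' @export
compare_conditions <- function(profile_a, profile_b, min_fl = 10,
                               fold_threshold = 2, include_tailed = FALSE) {
  if (!identical(sort(profile_a$ref_ids), sort(profile_b$ref_ids))) {
    stop("profiles were built against different reference sets")
  }
  ta <- tr_fl_table(profile_a, include_tailed)
  tb <- tr_fl_table(profile_b, include_tailed)
  tab <- merge(ta, tb, by = "mirna_id", suffixes = c("_a", "_b"))
  tab <- tab[tab$fl_a >= min_fl & tab$fl_b >= min_fl, , drop = FALSE]
  lfc <- ifelse(tab$ratio_a == 0 & tab$ratio_b == 0, 0,
                log2(tab$ratio_b / tab$ratio_a))
  flagged <- tab$ratio_b > fold_threshold * tab$ratio_a
  out <- data.frame(mirna_id = tab$mirna_id,
                    fl_a = tab$fl_a, fl_b = tab$fl_b,
                    ratio_a = tab$ratio_a, ratio_b = tab$ratio_b,
                    log2_fc = lfc, flagged = flagged,
                    stringsAsFactors = FALSE)
  out[order(out$mirna_id), , drop = FALSE]
}
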