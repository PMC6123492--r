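#' Capped-geometric accessibility model for AGO-bound 3' ends
#'
#' In an AGO1 immunoprecipitate the number of guide 3' nucleotides displaced
#' from the PAZ pocket (and hence accessible to the nuclease) varies per
#' molecule. The generator draws it from a geometric distribution on
#' \{0, 1, 2, ...\} with the given mean, capped at \code{cap}.
#'
#' @param mean mean of the uncapped geometric (default 3 nt).
#' @param cap maximum accessible nucleotides (default 6 nt).
#' @return an \code{accessibility_model} list.
#' @export
accessibility_model <- function(mean = 3, cap = 6L) {
  stopifnot(mean > 0, cap >= 0L)
  structure(list(mean = mean, cap = as.integer(cap)),
            class = "accessibility_model")
}

draw_accessibility <- function(acc, n) {
  pmin(stats::rgeom(n, prob = 1 / (1 + acc$mean)), acc$cap)
}

#' Generate a synthetic AGO1-IP small-RNA library
#'
#' Emulates sRNA-seq of AGO1-bound miRNAs after an in vitro trimming
#' reaction: per miRNA, \code{n_molecules} AGO-bound molecules are simulated
#' (3' accessibility drawn per molecule from \code{accessibility}), the
#' resulting (truncation, tail) states are recorded as ground truth, and
#' reads are emitted by multinomial sampling of species to the requested
#' depth. All reads share the mature 5' end.
#'
#' @param refs a \code{mirna_refs} reference set.
#' @param enz an \code{enzyme_params} (one condition).
#' @param tail_params a \code{tailing_params} or NULL.
#' @param depth total reads to sample for the library.
#' @param seed integer seed.
#' @param n_molecules simulated molecules per miRNA (default 2000).
#' @param accessibility an [accessibility_model()].
#' @param max_rounds encounter rounds per molecule.
#' @return list: \code{reads} (data.frame sequence, count), \code{truth}
#'   (data.frame mirna_id, t, tail, molecules), \code{seed}.
#' @export
generate_reads <- function(refs, enz, tail_params = tailing_params(),
                           depth = 50000L, seed = 1L, n_molecules = 2000L,
                           accessibility = accessibility_model(),
                           max_rounds = 50L) {
  stopifnot(inherits(refs, "mirna_refs"), depth >= 1L, n_molecules >= 1L)
  set.seed(seed)
  truth <- list()
  for (i in seq_len(nrow(refs))) {
    acc <- draw_accessibility(accessibility, n_molecules)
    t <- integer(n_molecules)
    tails <- character(n_molecules)
    for (j in seq_len(n_molecules)) {
      sub <- make_substrate(refs$sequence[i], overhang_3p = acc[j],
                            mode = "AGO_BOUND",
                            methylated = refs$methylated_3p[i])
      out <- simulate_molecule(sub, enz, tail_params, max_rounds)
      t[j] <- refs$length[i] - out$final_length
      tails[j] <- out$tail
    }
    agg <- stats::aggregate(list(molecules = rep(1L, n_molecules)),
                            by = list(t = t, tail = tails), FUN = sum)
    agg$mirna_id <- refs$id[i]
    truth[[i]] <- agg[, c("mirna_id", "t", "tail", "molecules")]
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$mirna_id, truth$t, nchar(truth$tail),
                       truth$tail), , drop = FALSE]
  rownames(truth) <- NULL
  # species sequences: templated prefix plus non-templated tail
  L <- refs$length[match(truth$mirna_id, refs$id)]
  prefix <- substr(refs$sequence[match(truth$mirna_id, refs$id)],
                   1L, L - truth$t)
  species <- paste0(prefix, truth$tail)
  sampled <- stats::rmultinom(1L, size = depth,
                              prob = truth$molecules)[, 1L]
  keep <- sampled > 0L
  reads <- stats::aggregate(list(count = sampled[keep]),
                            by = list(sequence = species[keep]), FUN = sum)
  list(reads = reads, truth = truth, seed = seed)
}

#' Ground-truth (t, m) frequency matrix for one miRNA
#'
#' Companion to [truncation_tailing_matrix()]: the simulator's own empirical
#' (truncation, tail-length) frequencies, for round-trip checks against the
#' profiler.
#'
#' @param truth ground-truth data.frame from [generate_reads()].
#' @param mirna_id reference id.
#' @param t_max,m_max axis caps.
#' @return proportion matrix over t = 0..t_max, m = 0..m_max.
#' @export
truth_matrix <- function(truth, mirna_id, t_max = 8L, m_max = 8L) {
  rows <- truth[truth$mirna_id == mirna_id, , drop = FALSE]
  mat <- matrix(0, nrow = t_max + 1L, ncol = m_max + 1L,
                dimnames = list(t = 0:t_max, m = 0:m_max))
  if (nrow(rows) == 0L || sum(rows$molecules) == 0) {
    mat[] <- NA_real_
    attr(mat, "empty") <- TRUE
    return(mat)
  }
  m <- nchar(rows$tail)
  for (i in seq_len(nrow(rows))) {
    mat[min(rows$t[i], t_max) + 1L, min(m[i], m_max) + 1L] <-
      mat[min(rows$t[i], t_max) + 1L, min(m[i], m_max) + 1L] +
      rows$molecules[i]
  }
  mat / sum(rows$molecules)
}
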