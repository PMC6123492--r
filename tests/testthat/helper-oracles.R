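# Shared test helpers: independent oracles and fixture generators.

rna_letters <- c("A", "C", "G", "U")

random_rna <- function(len) {
  paste(sample(rna_letters, len, replace = TRUE), collapse = "")
}

# Brute-force classification oracle: enumerate every (reference, t,
# tail-split) decomposition of the read and apply the tie-break order
# (max matched prefix q, then min t, then lexicographically smallest id).
# Deliberately independent of the longest-common-prefix implementation.
oracle_classify <- function(read, refs, q_min = 12L, t_max = 8L,
                            m_max = 8L) {
  best <- NULL
  for (i in seq_len(nrow(refs))) {
    L <- refs$length[i]
    for (t in 0:min(t_max, L)) {
      q <- L - t
      if (q < q_min || q > nchar(read)) next
      if (substr(read, 1L, q) != substr(refs$sequence[i], 1L, q)) next
      tail <- substr(read, q + 1L, nchar(read))
      if (nchar(tail) > m_max) next
      cand <- list(q = q, t = t, m = nchar(tail), tail = tail,
                   id = refs$id[i])
      if (is.null(best) ||
          cand$q > best$q ||
          (cand$q == best$q && cand$t < best$t) ||
          (cand$q == best$q && cand$t == best$t && cand$id < best$id)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(list(mirna_id = NA_character_, t = NA_integer_,
                tail = NA_character_, m = NA_integer_))
  }
  list(mirna_id = best$id, t = best$t, tail = best$tail, m = best$m)
}

# random reference sets and reads for property tests: a mix of
# reference-derived reads (random truncation/tail, sometimes ambiguous)
# and unrelated random reads
random_ref_set <- function(n_refs = 3L) {
  mirna_references(paste0("mir-", sprintf("%02d", seq_len(n_refs))),
                   vapply(seq_len(n_refs),
                          function(i) random_rna(sample(15:25, 1L)),
                          character(1L)))
}

random_read_for <- function(refs) {
  if (stats::runif(1L) < 0.15) {
    return(random_rna(sample(12:30, 1L)))
  }
  i <- sample(nrow(refs), 1L)
  L <- refs$length[i]
  t <- sample(0:min(9L, L - 10L), 1L)
  m <- sample(0:9L, 1L)
  tail <- if (m > 0L) {
    if (stats::runif(1L) < 0.5) strrep("U", m) else random_rna(m)
  } else ""
  paste0(substr(refs$sequence[i], 1L, L - t), tail)
}

# analytic accessible area of sphere 1 (radius R1) partially occluded by
# sphere 2 (radius R2) at centre distance d, for R1 - R2 < d < R1 + R2:
# the buried spherical cap has height h = R1 - (d^2 + R1^2 - R2^2) / (2 d)
two_sphere_accessible <- function(R1, R2, d) {
  a <- (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * (R1 - a)
}

# minimal PDB fixture from a compact atom spec
tiny_pdb <- function(atoms, path = tempfile(fileext = ".pdb"),
                     remarks = character()) {
  write_pdb(atoms, path, remarks)
  path
}

atom_row <- function(chain, resno, resname, atom, element, x, y, z,
                     occupancy = 1, b = 20, alt = "", het = FALSE) {
  data.frame(chain = chain, resno = resno, resname = resname, atom = atom,
             element = element, x = x, y = y, z = z, occupancy = occupancy,
             b = b, alt = alt, het = het, stringsAsFactors = FALSE)
}
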