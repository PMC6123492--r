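## Structure analysis: parsing, entity typing, SASA, interfaces, contacts.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL", "MSE", "SEC", "PYL")
RNA3 <- c("A", "C", "G", "U", "I", "RA", "RC", "RG", "RU",
          "1MA", "PSU", "OMC", "OMG", "OMU", "5MC", "5MU", "7MG", "M2G")
ION3 <- c("MG", "MN", "ZN", "NA", "K", "CA", "CL", "FE", "FE2", "NI",
          "CU", "CO", "CD")
WATER3 <- c("HOH", "WAT", "DOD")

classify_entity <- function(resname, overrides = NULL) {
  resname <- toupper(trimws(resname))
  ent <- rep("other", length(resname))
  ent[resname %in% AA3] <- "protein"
  ent[resname %in% RNA3] <- "rna"
  ent[resname %in% ION3] <- "ion"
  ent[resname %in% WATER3] <- "water"
  if (!is.null(overrides)) {
    hit <- match(resname, toupper(names(overrides)))
    ent[!is.na(hit)] <- unname(overrides[hit[!is.na(hit)]])
  }
  ent
}

parse_pdb_header <- function(lines) {
  num_after <- function(pattern) {
    hit <- grep(pattern, lines, value = TRUE)
    if (length(hit) == 0L) return(NA_real_)
    rest <- sub(pattern, "", hit[1L])
    m <- regmatches(rest, regexpr("[0-9]*\\.?[0-9]+", rest))
    if (length(m) == 0L) NA_real_ else as.numeric(m)
  }
  list(
    resolution = num_after("^REMARK   2 RESOLUTION\\."),
    r_work = num_after("^REMARK   3   R VALUE *\\(WORKING SET\\) *:"),
    r_free = num_after("^REMARK   3   FREE R VALUE +:")
  )
}

parse_cif_header <- function(lines) {
  num_tag <- function(tag) {
    hit <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (length(hit) == 0L) return(NA_real_)
    val <- trimws(sub(paste0("^", tag, "\\s+"), "", hit[1L]))
    suppressWarnings(as.numeric(gsub("[()'\"]", "", val)))
  }
  res <- num_tag("_refine\\.ls_d_res_high")
  if (is.na(res)) res <- num_tag("_reflns\\.d_resolution_high")
  list(resolution = res,
       r_work = num_tag("_refine\\.ls_R_factor_R_work"),
       r_free = num_tag("_refine\\.ls_R_factor_R_free"))
}

#' Load a macromolecular structure (PDB or mmCIF)
#'
#' Parses atom records (including HETATM) into a flat atom table, resolves
#' alternate locations by keeping the highest-occupancy conformer (ties by
#' altloc label order), types each residue as protein / RNA / ion / water /
#' other by residue-name dictionaries, and extracts header metadata
#' (resolution, R-work, R-free) when present. Parsing is delegated to
#' \pkg{bio3d}; header metadata is read from the raw records.
#'
#' @param path path to a PDB or mmCIF file.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or \code{"cif"}.
#' @param entity_overrides optional named character vector mapping residue
#'   names to entity types, overriding the built-in dictionaries.
#' @return a \code{structure_model}: list with \code{atoms} (data.frame:
#'   chain, resno, insert, resname, atom, element, x, y, z, occupancy, b,
#'   entity) and \code{metadata} (resolution, r_work, r_free, source).
#' @export
load_structure <- function(path, format = c("auto", "pdb", "cif"),
                           entity_overrides = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = , ent = "pdb", cif = , mmcif = "cif",
                     stop("cannot infer structure format from extension: ",
                          ext))
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "pdb") {
        bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
      } else {
        bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
      }),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("no atom records parsed from ", path)
  }
  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    resname = trimws(as.character(at$resid)),
    atom = trimws(as.character(at$elety)),
    element = toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy))),
    alt = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), NA_real_, at$b),
    stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in ", path)
  }
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1)) {
    stop("occupancy outside [0, 1] in ", path)
  }
  # infer missing element symbols from atom names (first alpha character,
  # honoring two-letter ions)
  miss <- atoms$element == ""
  if (any(miss)) {
    nm <- gsub("[^A-Za-z]", "", atoms$atom[miss])
    two <- toupper(nm) %in% ION3
    atoms$element[miss] <- ifelse(two, toupper(nm),
                                  toupper(substr(nm, 1L, 1L)))
  }
  # alternate locations: keep the highest-occupancy conformer per
  # (chain, resno, insert, atom name); ties resolved by altloc label order
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$atom, sep = "|")
  ord <- order(key, -atoms$occupancy, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$insert, atoms$atom), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  atoms$alt <- NULL
  atoms$entity <- classify_entity(atoms$resname, entity_overrides)
  lines <- readLines(path, warn = FALSE)
  meta <- if (format == "pdb") parse_pdb_header(lines) else
    parse_cif_header(lines)
  meta$source <- basename(path)
  model <- list(atoms = atoms, metadata = meta)
  class(model) <- "structure_model"
  model
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms (",
      paste(names(table(x$atoms$entity)), table(x$atoms$entity),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Domain partition of a protein chain
#'
#' @param ranges named list of \code{c(start, end)} residue-number ranges.
#'   The default partition is NTD 2-137, DEDDh 138-300, RRM 315-409.
#' @return a \code{domain_partition} object.
#' @export
domain_partition <- function(ranges = list(NTD = c(2, 137),
                                           DEDDh = c(138, 300),
                                           RRM = c(315, 409))) {
  stopifnot(length(ranges) >= 1L, !is.null(names(ranges)),
            all(nzchar(names(ranges))))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1L] > r[2L]) {
      stop("range ", nm, " must be c(start, end) with start <= end")
    }
  }
  mat <- do.call(rbind, ranges)
  ord <- order(mat[, 1L])
  if (any(mat[ord, 1L][-1L] <= mat[ord, 2L][-length(ranges)])) {
    stop("domain ranges overlap")
  }
  structure(ranges, class = "domain_partition")
}

#' Assign protein atoms to named domain ranges
#'
#' Every protein atom of the chosen chain is assigned to exactly one named
#' range or to \code{"unassigned"}. A named range selecting no atoms gives a
#' warning (crystallographic disorder), not an error.
#'
#' @param model a \code{structure_model}.
#' @param partition a [domain_partition()].
#' @param chain chain id; default the first chain containing protein atoms.
#' @return named list of integer atom-index vectors (rows of
#'   \code{model$atoms}), one per range plus \code{unassigned}.
#' @export
partition_domains <- function(model, partition = domain_partition(),
                              chain = NULL) {
  atoms <- model$atoms
  prot <- which(atoms$entity == "protein")
  if (is.null(chain)) {
    if (length(prot) == 0L) stop("model contains no protein atoms")
    chain <- atoms$chain[prot[1L]]
  }
  if (!chain %in% atoms$chain) stop("chain not present: ", chain)
  sel <- prot[atoms$chain[prot] == chain]
  out <- list()
  taken <- integer(0L)
  for (nm in names(partition)) {
    r <- partition[[nm]]
    idx <- sel[atoms$resno[sel] >= r[1L] & atoms$resno[sel] <= r[2L]]
    if (length(idx) == 0L) {
      warning("domain range ", nm, " selects no atoms (disorder?)")
    }
    out[[nm]] <- idx
    taken <- c(taken, idx)
  }
  out$unassigned <- setdiff(sel, taken)
  out
}

## -- Shrake-Rupley solvent-accessible surface area ------------------------

# published van-der-Waals radii (Bondi 1964, with nucleic-acid P), loaded
# from the package data file so the set is inspectable and overridable
vdw_radii_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "vdw_radii.tsv", package = "sdntrim")
      tab <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      cache <<- stats::setNames(tab$radius, toupper(tab$element))
    }
    cache
  }
})

atom_radii <- function(elements, radii = NULL) {
  tab <- vdw_radii_table()
  if (!is.null(radii)) tab[toupper(names(radii))] <- radii
  r <- tab[toupper(elements)]
  if (any(is.na(r))) {
    stop("no van-der-Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

# deterministic, near-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA: each atom is inflated by the probe radius and sampled with
#' a deterministic spherical point set; a point is accessible when it lies
#' outside every neighbouring inflated sphere. Waters and hydrogens are the
#' caller's responsibility (pass the atom subset to score).
#'
#' @param xyz numeric matrix (n x 3) of coordinates in Angstrom.
#' @param elements character vector of element symbols (length n).
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points sphere sample points per atom (default 960).
#' @param radii optional named numeric vector overriding table radii.
#' @return numeric vector of per-atom SASA in Angstrom^2; \code{sum()} gives
#'   the total.
#' @export
sasa <- function(xyz, elements, probe = 1.4, n_points = 960L, radii = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) == length(elements), nrow(xyz) >= 1L)
  R <- atom_radii(elements, radii) + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  out <- numeric(n)
  # neighbour search via squared-distance comparisons
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1L] - xyz[i, 1L])^2 + (xyz[, 2L] - xyz[i, 2L])^2 +
      (xyz[, 3L] - xyz[i, 3L])^2
    nb <- which(d2 < (R + R[i])^2 & d2 > 0)
    p <- pts * R[i]
    p[, 1L] <- p[, 1L] + xyz[i, 1L]
    p[, 2L] <- p[, 2L] + xyz[i, 2L]
    p[, 3L] <- p[, 3L] + xyz[i, 3L]
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj <- (p[free, 1L] - xyz[j, 1L])^2 + (p[free, 2L] - xyz[j, 2L])^2 +
        (p[free, 3L] - xyz[j, 3L])^2
      free[free] <- dj >= R[j]^2
    }
    out[i] <- 4 * pi * R[i]^2 * sum(free) / n_points
  }
  out
}

model_sasa <- function(model, idx, probe = 1.4, n_points = 960L) {
  a <- model$atoms[idx, , drop = FALSE]
  sum(sasa(cbind(a$x, a$y, a$z), a$element, probe, n_points))
}

#' Buried interface area between two atom sets
#'
#' \code{buried = SASA(A) + SASA(B) - SASA(A union B)}. Convention
#' \code{"pisa"} (default) reports \code{buried / 2} (the PISA-style
#' interface area); \code{"bsa"} reports the full buried area. The two
#' conventions differ exactly twofold. Waters are excluded by default.
#'
#' @param model a \code{structure_model}.
#' @param set_a,set_b disjoint integer vectors of atom indices (rows of
#'   \code{model$atoms}).
#' @param convention \code{"pisa"} or \code{"bsa"}.
#' @param probe,n_points passed to [sasa()].
#' @param exclude_water drop water atoms from both sets first.
#' @return interface area in Angstrom^2.
#' @export
interface_area <- function(model, set_a, set_b,
                           convention = c("pisa", "bsa"),
                           probe = 1.4, n_points = 960L,
                           exclude_water = TRUE) {
  convention <- match.arg(convention)
  if (length(intersect(set_a, set_b)) > 0L) {
    stop("atom sets overlap; interface is defined for disjoint sets")
  }
  if (exclude_water) {
    wa <- which(model$atoms$entity == "water")
    set_a <- setdiff(set_a, wa)
    set_b <- setdiff(set_b, wa)
  }
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("empty atom set after water exclusion")
  }
  buried <- model_sasa(model, set_a, probe, n_points) +
    model_sasa(model, set_b, probe, n_points) -
    model_sasa(model, c(set_a, set_b), probe, n_points)
  if (convention == "pisa") buried / 2 else buried
}

#' Protein-RNA contact map
#'
#' All inter-entity heavy-atom pairs within \code{generic_cutoff}; a contact
#' is flagged polar when both atoms are nitrogen or oxygen and within
#' \code{polar_cutoff}. Waters are excluded. The list is sorted by nucleotide
#' (chain, residue number) and then distance.
#'
#' @param model a \code{structure_model} containing protein and RNA.
#' @param polar_cutoff polar-contact distance cutoff in Angstrom (3.5).
#' @param generic_cutoff generic contact cutoff in Angstrom (4.0).
#' @return data.frame of contacts: protein chain/resno/resname/atom, RNA
#'   chain/resno/resname/atom, \code{distance}, \code{polar}. Empty (with a
#'   warning) when the model has no RNA.
#' @export
rna_protein_contacts <- function(model, polar_cutoff = 3.5,
                                 generic_cutoff = 4.0) {
  atoms <- model$atoms
  heavy <- atoms$element != "H"
  pi_ <- which(atoms$entity == "protein" & heavy)
  ri <- which(atoms$entity == "rna" & heavy)
  empty <- data.frame(protein_chain = character(), protein_resno = integer(),
                      protein_resname = character(), protein_atom = character(),
                      rna_chain = character(), rna_resno = integer(),
                      rna_resname = character(), rna_atom = character(),
                      distance = numeric(), polar = logical(),
                      stringsAsFactors = FALSE)
  if (length(pi_) == 0L) stop("model contains no protein atoms")
  if (length(ri) == 0L) {
    warning("model contains no RNA residues; empty contact list")
    return(empty)
  }
  px <- cbind(atoms$x[pi_], atoms$y[pi_], atoms$z[pi_])
  rx <- cbind(atoms$x[ri], atoms$y[ri], atoms$z[ri])
  hits <- list()
  for (k in seq_along(ri)) {
    d2 <- (px[, 1L] - rx[k, 1L])^2 + (px[, 2L] - rx[k, 2L])^2 +
      (px[, 3L] - rx[k, 3L])^2
    close <- which(d2 <= generic_cutoff^2)
    if (length(close) == 0L) next
    d <- sqrt(d2[close])
    ip <- pi_[close]
    polar <- atoms$element[ip] %in% c("N", "O") &
      atoms$element[ri[k]] %in% c("N", "O") & d <= polar_cutoff
    hits[[length(hits) + 1L]] <- data.frame(
      protein_chain = atoms$chain[ip], protein_resno = atoms$resno[ip],
      protein_resname = atoms$resname[ip], protein_atom = atoms$atom[ip],
      rna_chain = atoms$chain[ri[k]], rna_resno = atoms$resno[ri[k]],
      rna_resname = atoms$resname[ri[k]], rna_atom = atoms$atom[ri[k]],
      distance = d, polar = polar, stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$rna_chain, out$rna_resno, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count modeled RNA nucleotides
#'
#' @param model a \code{structure_model}.
#' @return number of residues typed as RNA.
#' @export
count_modeled_nucleotides <- function(model) {
  atoms <- model$atoms
  rna <- atoms[atoms$entity == "rna", , drop = FALSE]
  if (nrow(rna) == 0L) return(0L)
  length(unique(paste(rna$chain, rna$resno, rna$insert, sep = "|")))
}

#' Extract residue occupancies by residue name
#'
#' Occupancies are reported per matching residue, unmodified from the file
#' (for single-atom residues such as ions this is the atom occupancy; for
#' multi-atom residues the mean over atoms).
#'
#' @param model a \code{structure_model}.
#' @param resname residue-name filter, e.g. \code{"MG"}.
#' @return data.frame: \code{chain}, \code{resno}, \code{resname},
#'   \code{occupancy}. Empty when nothing matches.
#' @export
extract_occupancies <- function(model, resname) {
  atoms <- model$atoms
  hit <- atoms[toupper(atoms$resname) == toupper(resname), , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(data.frame(chain = character(), resno = integer(),
                      resname = character(), occupancy = numeric(),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(occupancy = hit$occupancy),
                          by = list(chain = hit$chain, resno = hit$resno,
                                    resname = hit$resname), FUN = mean)
  agg[order(agg$chain, agg$resno), , drop = FALSE]
}

#' Per-entity atom counts and mean B-factors
#'
#' @param model a \code{structure_model}.
#' @return data.frame with one row per entity class (protein, rna, ion,
#'   water, other): \code{n_atoms}, \code{mean_b}. Classes absent from the
#'   model are reported with zero atoms.
#' @export
model_statistics <- function(model) {
  classes <- c("protein", "rna", "ion", "water", "other")
  atoms <- model$atoms
  n <- vapply(classes, function(cl) sum(atoms$entity == cl), integer(1L))
  mb <- vapply(classes, function(cl) {
    b <- atoms$b[atoms$entity == cl]
    if (length(b) == 0L || all(is.na(b))) NA_real_ else mean(b, na.rm = TRUE)
  }, numeric(1L))
  data.frame(entity = classes, n_atoms = n, mean_b = mb,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fetch a PDB entry from the RCSB archive
#'
#' Convenience for desk-scale reproduction against deposited models; requires
#' network access.
#'
#' @param id 4-character PDB id.
#' @param dir download directory.
#' @param format \code{"pdb"} or \code{"cif"}.
#' @return path to the downloaded file.
#' @export
fetch_pdb <- function(id, dir = tempdir(), format = c("pdb", "cif")) {
  format <- match.arg(format)
  stopifnot(nchar(id) == 4L)
  dest <- file.path(dir, paste0(toupper(id), ".", format))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.%s", toupper(id),
                   format)
    status <- tryCatch(
      suppressWarnings(utils::download.file(url, dest, quiet = TRUE,
                                            mode = "wb")),
      error = function(e) -1L)
    if (!identical(status, 0L) || !file.exists(dest) ||
        file.size(dest) == 0L) {
      unlink(dest)
      stop("could not retrieve PDB entry ", toupper(id), " from ", url,
           " (network unavailable?)")
    }
  }
  dest
}
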