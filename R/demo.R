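#' Write a minimal PDB file from an atom table
#'
#' Fixed-format ATOM/HETATM records plus optional REMARK header lines.
#' Intended for writing small synthetic fixtures and round-tripping models;
#' not a general deposition writer.
#'
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resname}, \code{atom}, \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{occupancy}, \code{b}; optional \code{alt} (altloc
#'   character) and \code{het} (logical, write as HETATM).
#' @param path output path.
#' @param remarks character vector of raw header lines written verbatim
#'   before the coordinates.
#' @return the path, invisibly.
#' @export
write_pdb <- function(atoms, path, remarks = character()) {
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z",
            "occupancy", "b")
  stopifnot(all(need %in% names(atoms)))
  alt <- if ("alt" %in% names(atoms)) atoms$alt else rep("", nrow(atoms))
  het <- if ("het" %in% names(atoms)) atoms$het else rep(FALSE, nrow(atoms))
  name4 <- ifelse(nchar(atoms$atom) >= 4L, substr(atoms$atom, 1L, 4L),
                  sprintf(" %-3s", atoms$atom))
  rec <- sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 ifelse(het, "HETATM", "ATOM"), seq_len(nrow(atoms)), name4,
                 substr(paste0(alt, " "), 1L, 1L), atoms$resname,
                 atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z,
                 atoms$occupancy, atoms$b, atoms$element)
  writeLines(c(remarks, rec, "END"), path)
  invisible(path)
}

#' Synthetic protein-RNA demonstration complex
#'
#' A small, entirely synthetic structure in the geometry of a DEDDh
#' nuclease-RNA complex, for demonstrating and smoke-testing the structure
#' stage without any deposited model: two protein residue clusters (residue
#' numbers falling in the default NTD and DEDDh ranges, plus residue 310 in
#' the inter-domain gap and residue 350 in the RRM range), a 4-nt RNA chain
#' whose 3'-terminal nucleotide contacts an arginine side chain, two Mg ions
#' with distinct occupancies, an altloc pair, and waters. Coordinates are
#' fixed constants, not drawn from any deposited entry.
#'
#' @return atom data.frame suitable for [write_pdb()].
#' @export
demo_structure_atoms <- function() {
  row <- function(chain, resno, resname, atom, element, x, y, z,
                  occupancy = 1, b = 30, alt = "", het = FALSE) {
    data.frame(chain = chain, resno = resno, resname = resname, atom = atom,
               element = element, x = x, y = y, z = z,
               occupancy = occupancy, b = b, alt = alt, het = het,
               stringsAsFactors = FALSE)
  }
  backbone <- function(resno, resname, x0, y0, b = 30) {
    rbind(row("A", resno, resname, "N", "N", x0, y0, 0, b = b),
          row("A", resno, resname, "CA", "C", x0 + 1.2, y0, 0.6, b = b),
          row("A", resno, resname, "C", "C", x0 + 2.4, y0, 0, b = b),
          row("A", resno, resname, "O", "O", x0 + 2.4, y0 + 1.1, -0.6,
              b = b))
  }
  rbind(
    # NTD-like cluster (residue numbers within 2-137)
    backbone(96, "GLU", 0, 0), backbone(100, "LEU", 4, 0),
    backbone(104, "TYR", 8, 0), backbone(123, "PHE", 12, 0, b = 40),
    # DEDDh-like cluster (within 138-300), 5 Angstrom away: the two rows
    # bury surface against each other
    backbone(185, "ARG", 0, 5), backbone(200, "ASP", 4, 5),
    backbone(223, "HIS", 8, 5), backbone(224, "SER", 12, 5),
    # linker residue (gap 301-314) and an RRM-range residue, off to the side
    backbone(310, "GLY", 30, 0), backbone(350, "PHE", 34, 0),
    # side-chain atoms making defined protein-RNA contacts
    row("A", 185, "ARG", "NH1", "N", 2.0, 8.6, 0.0),  # 2.86 A to G4 O2'
    row("A", 223, "HIS", "NE2", "N", 8.6, 8.2, 0.0),  # 3.01 A to C3 OP1
    row("A", 224, "SER", "OG", "O", 12.6, 8.7, 0.0, occupancy = 0.6,
        alt = "A"),                                    # 2.90 A to C3 O2'
    row("A", 224, "SER", "OG", "O", 12.6, 8.7, 2.5, occupancy = 0.4,
        alt = "B"),
    row("A", 200, "ASP", "CB", "C", 4.6, 8.9, 0.0),   # 3.30 A to A2 C1'
    # 4-nt RNA chain, 3'-terminal G nearest the "catalytic" cluster
    row("B", 1, "U", "P", "P", 16.0, 13.0, 0.0, b = 60),
    row("B", 1, "U", "C1'", "C", 15.0, 12.8, 0.6, b = 60),
    row("B", 1, "U", "O2'", "O", 14.2, 13.4, 0.0, b = 60),
    row("B", 2, "A", "P", "P", 5.0, 12.6, 0.0, b = 55),
    row("B", 2, "A", "C1'", "C", 4.6, 12.2, 0.0, b = 55),
    row("B", 2, "A", "O2'", "O", 5.4, 13.0, 0.6, b = 55),
    row("B", 3, "C", "P", "P", 8.6, 11.4, 0.0, b = 50),
    row("B", 3, "C", "OP1", "O", 8.6, 11.0, 1.1, b = 50),
    row("B", 3, "C", "O2'", "O", 12.6, 11.6, 0.0, b = 50),
    row("B", 4, "G", "P", "P", 2.0, 12.8, 0.0, b = 45),
    row("B", 4, "G", "C1'", "C", 2.0, 11.6, 0.8, b = 45),
    row("B", 4, "G", "O2'", "O", 2.0, 11.4, -0.6, b = 45),
    row("B", 4, "G", "O3'", "O", 2.8, 12.0, 1.2, b = 45),
    # metals and waters
    row("C", 501, "MG", "MG", "MG", 3.4, 10.4, 0.6, occupancy = 0.60,
        b = 70, het = TRUE),
    row("C", 502, "MG", "MG", "MG", 6.6, 10.2, 0.3, occupancy = 1.00,
        b = 65, het = TRUE),
    row("W", 601, "HOH", "O", "O", 20, 20, 20, b = 40, het = TRUE),
    row("W", 602, "HOH", "O", "O", 24, 20, 20, b = 42, het = TRUE))
}

#' Write the synthetic demonstration complex to a PDB file
#'
#' See [demo_structure_atoms()]; the file carries resolution / R-work /
#' R-free header remarks so header parsing can be exercised. All values are
#' synthetic.
#'
#' @param path output path (default: \code{synthetic_complex.pdb} in a
#'   temporary directory).
#' @return the path, invisibly.
#' @export
write_demo_structure <- function(path = file.path(tempdir(),
                                                  "synthetic_complex.pdb")) {
  remarks <- c(
    "REMARK   1 SYNTHETIC DEMONSTRATION COMPLEX (NOT A DEPOSITED MODEL)",
    "REMARK   2 RESOLUTION.    2.80 ANGSTROMS.",
    "REMARK   3   R VALUE            (WORKING SET) : 0.210",
    "REMARK   3   FREE R VALUE                     : 0.245")
  write_pdb(demo_structure_atoms(), path, remarks)
}
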