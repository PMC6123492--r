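#' Weighted-average chemical shift perturbations from an HSQC titration
#'
#' For each backbone amide observed in the reference spectrum, the weighted
#' average perturbation is
#' \deqn{\Delta\delta_{avg} = \sqrt{\Delta\delta_H^2 + (0.2\,\Delta\delta_N)^2}}
#' where the differences are titrated minus reference shifts in ppm. A
#' residue is \code{perturbed} when \eqn{\Delta\delta_{avg}} strictly exceeds
#' the threshold (default 0.05 ppm), \code{disappeared} when its cross-peak is
#' observed in the reference but missing from the titrated spectrum, and
#' \code{unperturbed} otherwise. A residue present in the titrated table but
#' not in the reference is a consistency error.
#'
#' @param reference,titrated shift tables (data.frames with columns
#'   \code{residue}, \code{dH}, \code{dN}; see [read_shift_table()]).
#' @param threshold perturbation threshold in ppm (> 0).
#' @return data.frame: \code{residue}, \code{d_dH}, \code{d_dN},
#'   \code{d_avg}, \code{status} (NA shift differences for disappeared
#'   residues).
#' @export
compute_csp <- function(reference, titrated, threshold = 0.05) {
  stopifnot(threshold > 0)
  for (tab in list(reference, titrated)) {
    if (!all(c("residue", "dH", "dN") %in% names(tab))) {
      stop("shift tables need columns residue, dH, dN")
    }
  }
  extra <- setdiff(titrated$residue, reference$residue)
  if (length(extra) > 0L) {
    stop("residues in titrated spectrum absent from reference: ",
         paste(extra, collapse = ", "))
  }
  idx <- match(reference$residue, titrated$residue)
  seen <- !is.na(idx)
  d_dH <- ifelse(seen, titrated$dH[idx] - reference$dH, NA_real_)
  d_dN <- ifelse(seen, titrated$dN[idx] - reference$dN, NA_real_)
  d_avg <- ifelse(seen, sqrt(d_dH^2 + (0.2 * d_dN)^2), NA_real_)
  status <- ifelse(!seen, "disappeared",
                   ifelse(d_avg > threshold, "perturbed", "unperturbed"))
  data.frame(residue = reference$residue, d_dH = d_dH, d_dN = d_dN,
             d_avg = d_avg, status = status, stringsAsFactors = FALSE)
}
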