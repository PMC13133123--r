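# Storage-density and mass/redundancy arithmetic.  Densities are
# payload bytes per gram of DNA in decimal exabytes (10^18 bytes),
# assuming double-stranded DNA with a molecular weight of
# 662 g mol^-1 bp^-1 by default; at 2 bit/nt and one copy per sequence
# this gives the theoretical maximum of ~227 EB/g.

N_AVOGADRO <- 6.02214076e23

#' Payload storage density
#'
#' `D = rho * N_A / (R * M * 8 * 1e18)` EB per gram for the payload-only
#' basis; the `with_adapters` basis scales by the payload fraction of
#' the total sequence length.
#'
#' @param rho Code rate in bit per nt.
#' @param redundancy Physical redundancy R (mean oligo copies per
#'   sequence).
#' @param mw Molecular weight in g per mol per bp (default 662).
#' @param basis `"payload_only"` or `"with_adapters"`.
#' @param payload_nt,total_nt Payload and total sequence lengths in nt
#'   (required for the `with_adapters` basis).
#' @return A `density_report`: list with `density_EB_per_g` and the
#'   inputs.
#' @export
#' @examples
#' storage_density(2, 1)$density_EB_per_g      # ~227
#' storage_density(1.85, 32)$density_EB_per_g  # ~6.6
storage_density <- function(rho, redundancy, mw = 662,
                            basis = c("payload_only", "with_adapters"),
                            payload_nt = NULL, total_nt = NULL) {
  basis <- match.arg(basis)
  if (!(rho > 0 && redundancy > 0 && mw > 0)) {
    stop("rho, redundancy and mw must all be positive")
  }
  d <- rho * N_AVOGADRO / (redundancy * mw * 8 * 1e18)
  if (basis == "with_adapters") {
    if (is.null(payload_nt) || is.null(total_nt)) {
      stop("with_adapters basis needs payload_nt and total_nt")
    }
    stopifnot(payload_nt > 0, total_nt >= payload_nt)
    d <- d * payload_nt / total_nt
  }
  structure(list(density_EB_per_g = d, rho = rho, redundancy = redundancy,
                 mw = mw, basis = basis),
            class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("<density_report> %.3g EB/g (rho %.3g bit/nt, R %.3g, MW %g)\n",
              x$density_EB_per_g, x$rho, x$redundancy, x$mw))
  invisible(x)
}

#' Physical redundancy contained in a DNA mass
#'
#' `redundancy = mass * N_A / (n_seqs * length_nt * mw)`, with the mass
#' given in nanograms.
#'
#' @param n_seqs Number of distinct designed sequences.
#' @param length_nt Sequence length in nt (bp for double-stranded DNA).
#' @param mass_ng DNA mass in ng.
#' @param mw Molecular weight in g per mol per bp (default 662).
#' @return Mean copies per designed sequence (numeric scalar).
#' @export
#' @examples
#' redundancy_mass(11293, 170, mass_ng = 1)  # ~4.7e5 copies per sequence
redundancy_mass <- function(n_seqs, length_nt, mass_ng, mw = 662) {
  if (!(n_seqs > 0 && length_nt > 0 && mass_ng > 0 && mw > 0)) {
    stop("all arguments must be positive")
  }
  (mass_ng * 1e-9) * N_AVOGADRO / (n_seqs * length_nt * mw)
}
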