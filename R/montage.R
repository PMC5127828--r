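#' Standard 22-channel clinical montage (10-20 system)
#'
#' Channel labels of the 22-electrode clinical montage used throughout the
#' package: the 19 standard 10-20 placements (with T3/T4/T5/T6 naming for
#' the temporal sites) plus the mastoids M1 and M2. Mastoids are treated as
#' analysis channels, not as a reference.
#'
#' @return Character vector of 22 channel labels.
#' @export
#' @examples
#' montage_channels()
montage_channels <- function() {
  c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2", "M1", "M2")
}

#' Posterior channels of the montage
#'
#' The parieto-occipital subset where the posterior dominant (alpha) rhythm
#' is strongest and where Alzheimer-type slowing is expressed.
#'
#' @return Character vector of 7 channel labels.
#' @export
posterior_channels <- function() {
  c("T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Names of the six spectral parameters
#'
#' Order used everywhere a per-channel parameter vector appears:
#' `S` (low-frequency power scale, uV^2), `k` (1/f decay exponent),
#' `A` (alpha peak amplitude, uV^2), `c` (alpha center frequency, Hz),
#' `w` (alpha dispersion, Hz), `b` (baseline offset, uV^2).
#'
#' @return Character vector of length 6.
#' @export
param_names <- function() c("S", "k", "A", "c", "w", "b")

# hard parameter bounds shared by generator and fitter
.param_lower <- c(S = 0, k = 0, A = 0, c = 6, w = 0.3, b = 0)
.param_upper <- c(S = Inf, k = 5, A = Inf, c = 14, w = 5, b = Inf)
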