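#' Amino-acid constants used by the coarse-grained model
#'
#' One-letter codes of the 20 standard amino acids in alphabetical order.
#' All per-residue parameter tables in the package are indexed in this order.
#'
#' @format Character vector of length 20.
#' @export
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle hydropathy, used to build the default side-chain contact
# matrix. Indexed like AA_CODES.
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Distance (Angstrom) from C-alpha to the united side-chain centre, one value
# per residue type, derived from idealized residue geometry (a simplification
# of database-derived placement tables). Glycine has no side chain (centre at
# C-alpha); Alanine's centre coincides with C-beta.
SC_DISTANCE <- c(
  A = 1.53, C = 2.10, D = 2.50, E = 3.10, F = 3.40,
  G = 0.00, H = 3.20, I = 2.30, K = 3.50, L = 2.60,
  M = 3.00, N = 2.50, P = 1.90, Q = 3.10, R = 4.10,
  S = 1.90, T = 1.90, V = 2.00, W = 3.90, Y = 3.90
)

CB_DISTANCE <- 1.53

#' Convert one-letter amino-acid codes to table indices
#'
#' @param aa character vector of one-letter codes (or a single string).
#' @return Integer vector of indices into [AA_CODES].
#' @keywords internal
aa_index <- function(aa) {
  if (length(aa) == 1L && nchar(aa) > 1L) aa <- strsplit(aa, "")[[1]]
  idx <- match(toupper(aa), AA_CODES)
  if (anyNA(idx)) {
    bad <- unique(aa[is.na(idx)])
    stop("invalid amino-acid code(s): ", paste(bad, collapse = ", "))
  }
  idx
}
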