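# Extended principal-property scales (z1..z5) for the 20 standard amino
# acids (Sandberg et al., J Med Chem 1998). z1 tracks lipophilicity, z2
# steric bulk/polarizability, z3 polarity, z4/z5 electronic effects.
.zscales <- matrix(c(
  #  z1     z2     z3     z4     z5
   0.24, -2.32,  0.60, -0.14,  1.30,  # A
   3.52,  2.50, -3.50,  1.99, -0.17,  # R
   3.05,  1.62,  1.04, -1.15,  1.61,  # N
   3.98,  0.93,  1.93, -2.46,  0.75,  # D
   0.84, -1.67,  3.71,  0.18, -2.65,  # C
   1.75,  0.50, -1.44, -1.34,  0.66,  # Q
   3.11,  0.26, -0.11, -3.04, -0.25,  # E
   2.05, -4.06,  0.36, -0.82, -0.38,  # G
   2.47,  1.95,  0.26,  3.90,  0.09,  # H
  -3.89, -1.73, -1.71, -0.84,  0.26,  # I
  -4.28, -1.30, -1.49, -0.72,  0.84,  # L
   2.29,  0.89, -2.49,  1.49,  0.31,  # K
  -2.85, -0.22,  0.47,  1.94, -0.98,  # M
  -4.22,  1.94,  1.06,  0.54, -0.62,  # F
  -1.66,  0.27,  1.84,  0.70,  2.00,  # P
   2.39, -1.07,  1.15, -1.39,  0.67,  # S
   0.75, -2.18, -1.12, -1.46, -0.40,  # T
  -4.36,  3.94,  0.59,  3.44, -1.59,  # W
  -2.54,  2.44,  0.43,  0.04, -1.47,  # Y
  -2.59, -2.64, -1.54, -0.85, -0.02   # V
), nrow = 20, byrow = TRUE,
dimnames = list(
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  paste0("z", 1:5)
))

#' Amino-acid z-scale constants
#'
#' The five extended principal-property scales for the 20 standard residues,
#' as a 20 x 5 matrix keyed by one-letter code. The values are immutable
#' package constants.
#'
#' @return Numeric matrix with residue row names and columns `z1`..`z5`.
#' @export
zscale_matrix <- function() .zscales

#' @rdname zscale_matrix
#' @return `zscale_table()` returns the same constants as a tibble with an
#'   `aa` column.
#' @export
zscale_table <- function() {
  tibble::as_tibble(.zscales, rownames = "aa")
}
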