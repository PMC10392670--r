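## Standard base geometries in the standard reference frame (base in the
## x-y plane, origin on the pseudo-dyad, y axis towards the attached
## backbone). Used both to fit observed bases (Kabsch superposition) and to
## rebuild idealized coordinates from helical parameters.

STANDARD_BASES <- list(
  A = matrix(c(
    -2.479, 5.346, 0.000,   # C1'
    -1.291, 4.498, 0.000,   # N9
     0.024, 4.897, 0.000,   # C8
     0.877, 3.902, 0.000,   # N7
     0.071, 2.771, 0.000,   # C5
     0.369, 1.398, 0.000,   # C6
     1.611, 0.909, 0.000,   # N6
    -0.668, 0.532, 0.000,   # N1
    -1.912, 1.023, 0.000,   # C2
    -2.320, 2.290, 0.000,   # N3
    -1.267, 3.124, 0.000),  # C4
    ncol = 3, byrow = TRUE,
    dimnames = list(c("C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1",
                      "C2", "N3", "C4"), c("x", "y", "z"))),
  C = matrix(c(
    -2.477, 5.402, 0.000,
    -1.285, 4.542, 0.000,
    -1.472, 3.158, 0.000,
    -2.628, 2.709, 0.001,
    -0.391, 2.344, 0.000,
     0.837, 2.868, 0.000,
     1.875, 2.027, 0.001,
     1.056, 4.275, 0.000,
    -0.023, 5.068, 0.000),
    ncol = 3, byrow = TRUE,
    dimnames = list(c("C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
                    c("x", "y", "z"))),
  G = matrix(c(
    -2.477, 5.399, 0.000,
    -1.289, 4.551, 0.000,
     0.023, 4.962, 0.000,
     0.870, 3.969, 0.000,
     0.071, 2.833, 0.000,
     0.424, 1.460, 0.000,
     1.554, 0.955, 0.000,
    -0.700, 0.641, 0.000,
    -1.999, 1.087, 0.000,
    -2.949, 0.139, -0.001,
    -2.342, 2.364, 0.001,
    -1.265, 3.177, 0.000),
    ncol = 3, byrow = TRUE,
    dimnames = list(c("C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1",
                      "C2", "N2", "N3", "C4"), c("x", "y", "z"))),
  T = matrix(c(
    -2.481, 5.354, 0.000,
    -1.284, 4.500, 0.000,
    -1.462, 3.135, 0.000,
    -2.562, 2.608, 0.000,
    -0.298, 2.407, 0.000,
     0.994, 2.897, 0.000,
     1.944, 2.119, 0.000,
     1.106, 4.338, 0.000,
     2.466, 4.961, 0.001,
    -0.024, 5.057, 0.000),
    ncol = 3, byrow = TRUE,
    dimnames = list(c("C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5",
                      "C7", "C6"), c("x", "y", "z")))
)

## Ring atoms used for the reference-frame fit.
BASE_RING_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6")
)

## Watson-Crick heavy-atom hydrogen-bond pairs, Watson base first.
WC_HBOND_PAIRS <- list(
  `A:T` = list(c("N6", "O4"), c("N1", "N3")),
  `T:A` = list(c("O4", "N6"), c("N3", "N1")),
  `G:C` = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")),
  `C:G` = list(c("N4", "O6"), c("N3", "N1"), c("O2", "N2"))
)

COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

#' Complement a DNA sequence
#'
#' @param sequence Character string over ACGT.
#' @param reverse Reverse as well (default TRUE: reverse complement).
#' @return Character string.
#' @export
complement_sequence <- function(sequence, reverse = TRUE) {
  b <- strsplit(toupper(sequence), "")[[1]]
  if (!all(b %in% names(COMPLEMENT)))
    stop("sequence contains non-ACGT characters")
  comp <- COMPLEMENT[b]
  paste(if (reverse) rev(comp) else comp, collapse = "")
}

#' Fit a base reference frame to observed heavy atoms
#'
#' Least-squares (Kabsch) superposition of the embedded standard base
#' geometry onto the observed ring atoms; the fitted rigid transform is the
#' base frame. Deterministic: the frame minimizes the RMSD between observed
#' and standard ring atoms.
#'
#' @param base_atoms Numeric matrix of heavy-atom coordinates (Angstrom)
#'   with atom names as rownames; must include all ring atoms of the base.
#' @param base_type One of "A", "C", "G", "T".
#' @return A `base_frame`.
#' @export
fit_base_frame <- function(base_atoms, base_type) {
  base_type <- toupper(base_type)
  if (!base_type %in% names(STANDARD_BASES))
    stop("unknown base type: ", base_type)
  ring <- BASE_RING_ATOMS[[base_type]]
  missing <- setdiff(ring, rownames(base_atoms))
  if (length(missing))
    stop(sprintf("missing ring atom(s) for base %s: %s", base_type,
                 paste(missing, collapse = ", ")))
  obs <- base_atoms[ring, , drop = FALSE]
  std <- STANDARD_BASES[[base_type]][ring, , drop = FALSE]
  co <- colMeans(obs); cs <- colMeans(std)
  H <- crossprod(sweep(std, 2, cs), sweep(obs, 2, co))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  base_frame(origin = as.numeric(co - R %*% cs), axes = R)
}
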