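# Amino-acid feature tables: polarizability (P), isoelectric point (I) and
# hydrophobicity (H) drive the RGB colouring of interface images; circle radii
# derive from mean residue volumes.

# Mean residue volumes in cubic Angstrom (Zamyatnin-type consensus values);
# radius of the equivalent sphere is used as the circle radius in residue mode.
.aa_volumes <- c(
  A = 88.6,  R = 173.4, N = 114.1, D = 111.1, C = 108.5,
  Q = 143.8, E = 138.4, G = 60.1,  H = 153.2, I = 166.7,
  L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
  S = 89.0,  T = 116.1, W = 227.8, Y = 193.6, V = 140.0
)

.aaindex_scale <- function(accession) {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  entry <- env$aaindex[[accession]]
  vals <- entry$I
  # seqinr names values by three-letter code
  names(vals) <- vapply(names(vals), function(a) bio3d::aa321(toupper(a)), "")
  vals
}

.minmax <- function(x) (x - min(x)) / (max(x) - min(x))

#' Amino-acid feature table
#'
#' Returns the per-residue physicochemical features used to colour interface
#' images: side-chain polarizability (P, Charton-Charton), isoelectric point
#' (I, Zimmerman) and hydrophobicity (H, Kyte-Doolittle hydropathy), each
#' min-max scaled to \[0, 1\] over the 20 standard amino acids, plus the circle
#' radius in Angstrom derived from the mean residue volume as
#' \eqn{r = (3V/4\pi)^{1/3}}.
#'
#' The three scaled features map directly onto the red, green and blue channel
#' of a residue's circle. The raw (unscaled) values are retained in `*_raw`
#' columns so alternative scalings can be applied downstream.
#'
#' @return A tibble with one row per standard amino acid: `aa` (one-letter
#'   code), `P`, `I`, `H` in \[0,1\], `radius` in Angstrom, and raw columns.
#' @export
#' @examples
#' feature_table()
feature_table <- function() {
  aas <- names(.aa_volumes)
  P <- .aaindex_scale("CHAM820101")[aas]
  I <- .aaindex_scale("ZIMJ680104")[aas]
  H <- .aaindex_scale("KYTJ820101")[aas]
  tibble(
    aa = aas,
    P = .minmax(P), I = .minmax(I), H = .minmax(H),
    radius = (3 * .aa_volumes / (4 * pi))^(1 / 3),
    P_raw = unname(P), I_raw = unname(I), H_raw = unname(H),
    volume = unname(.aa_volumes)
  )
}

# cached copy; the table is deterministic
.feature_cache <- new.env(parent = emptyenv())

.features <- function() {
  if (is.null(.feature_cache$tbl)) .feature_cache$tbl <- feature_table()
  .feature_cache$tbl
}
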