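#' Amino-acid scales used by the feature engine
#'
#' A single documented set of conventions: Kyte-Doolittle hydropathy,
#' average (isotope-averaged) residue masses, EMBOSS pKa values for the
#' ionizable groups, and the eight-residue-class partition used by the
#' blockiness statistic. These are configuration data; every feature
#' function reads them from here so an alternative convention can be swapped
#' in one place.
#'
#' @return A list with elements `hydropathy` (named numeric, Kyte-Doolittle
#'   units), `residue_mass` (named numeric, Da; add `water_mass` once per
#'   chain), `water_mass` (Da), `pka` (named numeric: side chains D,E,C,Y,H,K,R
#'   plus `Nterm`, `Cterm`; EMBOSS values), and `residue_classes` (named list
#'   of residue vectors: polar, hydrophobic, positive, negative, aromatic,
#'   alanine, proline, glycine).
#' @export
aa_scales <- function() {
  list(
    hydropathy = c(
      A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
      Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
      L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
      S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2),
    residue_mass = c(
      A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
      E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
      L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
      S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326),
    water_mass = 18.01524,
    pka = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1, H = 6.5, K = 10.8, R = 12.5,
            Nterm = 8.6, Cterm = 3.6),
    residue_classes = list(
      polar       = c("S", "T", "N", "Q", "C", "H"),
      hydrophobic = c("I", "L", "M", "V"),
      positive    = c("R", "K"),
      negative    = c("D", "E"),
      aromatic    = c("F", "W", "Y"),
      alanine     = "A",
      proline     = "P",
      glycine     = "G")
  )
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
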