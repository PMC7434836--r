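#' @keywords internal
#' @importFrom rlang .data %||%
#' @importFrom ranger ranger
#' @importFrom e1071 svm
"_PACKAGE"

## Alphabet: the 20 standard amino acids in lexicographic order. All encoder
## feature orderings derive from this vector.
AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## 5-way physicochemical grouping used by the grouped-composition family
## (GAAC, GDPC, GTPC, CKSAAGP).
GAAC_GROUPS <- list(
  aliphatic      = c("G", "A", "V", "L", "M", "I"),
  aromatic       = c("F", "Y", "W"),
  positivecharge = c("K", "R", "H"),
  negativecharge = c("D", "E"),
  uncharged      = c("S", "T", "C", "P", "N", "Q")
)

## Conjoint-triad 7-class partition (original conjoint-triad convention:
## classes by side-chain volume and dipole).
CT_CLASSES <- list(
  c("A", "G", "V"),
  c("I", "L", "F", "P"),
  c("Y", "M", "T", "S"),
  c("H", "N", "Q", "W"),
  c("R", "K"),
  c("D", "E"),
  c("C")
)

## Composition/Transition/Distribution descriptors: 13 properties, each
## partitioning the 20 residues into 3 groups. Standard 3-group tables
## (Dubchak-style) as used by the common descriptor toolkits; the property
## names are the ones the feature-name grammar exposes.
CTD_PROPERTIES <- list(
  hydrophobicity_PRAM900101 = list(
    g1 = c("R", "K", "E", "D", "Q", "N"),
    g2 = c("G", "A", "S", "T", "P", "H", "Y"),
    g3 = c("C", "L", "V", "I", "M", "F", "W")),
  hydrophobicity_ARGP820101 = list(
    g1 = c("Q", "S", "T", "N", "G", "D", "E"),
    g2 = c("R", "A", "H", "C", "K", "M", "V"),
    g3 = c("L", "Y", "P", "F", "I", "W")),
  hydrophobicity_ZIMJ680101 = list(
    g1 = c("Q", "N", "G", "S", "W", "T", "D", "E", "R", "A"),
    g2 = c("H", "M", "C", "K", "V"),
    g3 = c("L", "P", "F", "Y", "I")),
  hydrophobicity_PONP930101 = list(
    g1 = c("K", "P", "D", "E", "S", "N", "Q", "T"),
    g2 = c("G", "R", "H", "A"),
    g3 = c("Y", "M", "F", "W", "L", "C", "V", "I")),
  hydrophobicity_CASG920101 = list(
    g1 = c("K", "D", "E", "Q", "P", "S", "R", "N", "T", "G"),
    g2 = c("A", "H", "Y", "M", "L", "V"),
    g3 = c("F", "I", "W", "C")),
  hydrophobicity_ENGD860101 = list(
    g1 = c("R", "D", "K", "E", "N", "Q", "H", "Y", "P"),
    g2 = c("S", "G", "T", "A", "W"),
    g3 = c("C", "V", "L", "I", "M", "F")),
  hydrophobicity_FASG890101 = list(
    g1 = c("K", "E", "R", "S", "Q", "D"),
    g2 = c("N", "T", "P", "G"),
    g3 = c("A", "Y", "H", "W", "V", "M", "F", "L", "I", "C")),
  normwaalsvolume = list(
    g1 = c("G", "A", "S", "T", "P", "D", "C"),
    g2 = c("N", "V", "E", "Q", "I", "L"),
    g3 = c("M", "H", "K", "F", "R", "Y", "W")),
  polarity = list(
    g1 = c("L", "I", "F", "W", "C", "M", "V", "Y"),
    g2 = c("P", "A", "T", "G", "S"),
    g3 = c("H", "Q", "R", "K", "N", "E", "D")),
  polarizability = list(
    g1 = c("G", "A", "S", "D", "T"),
    g2 = c("C", "P", "N", "V", "E", "Q", "I", "L"),
    g3 = c("K", "M", "H", "F", "R", "Y", "W")),
  charge = list(
    g1 = c("K", "R"),
    g2 = c("A", "N", "C", "Q", "G", "H", "I", "L", "M", "F",
           "P", "S", "T", "W", "Y", "V"),
    g3 = c("D", "E")),
  secondarystruct = list(
    g1 = c("E", "A", "L", "M", "Q", "K", "R", "H"),
    g2 = c("V", "I", "Y", "C", "W", "F", "T"),
    g3 = c("G", "N", "P", "S", "D")),
  solventaccess = list(
    g1 = c("A", "L", "F", "C", "G", "I", "V", "W"),
    g2 = c("R", "K", "Q", "E", "N", "D"),
    g3 = c("M", "P", "S", "T", "H", "Y"))
)

## Per-residue numeric scales for pseudo amino acid composition (classic
## pseudo-AAC values: hydrophobicity, hydrophilicity, side-chain mass).
PAAC_SCALES <- list(
  Hydrophobicity = c(
    A =  0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19,
    G =  0.48, H = -0.40, I = 1.38, K = -1.50, L = 1.06,
    M =  0.64, N = -0.78, P = 0.12, Q = -0.85, R = -2.53,
    S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26),
  Hydrophilicity = c(
    A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5,
    G =  0.0, H = -0.5, I = -1.8, K = 3.0, L = -1.8,
    M = -1.3, N =  0.2, P = 0.0, Q = 0.2, R = 3.0,
    S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3),
  SideChainMass = c(
    A =  15, C =  47, D =  59, E =  73, F =  91,
    G =   1, H =  82, I =  57, K =  73, L =  57,
    M =  75, N =  58, P =  42, Q =  72, R = 101,
    S =  31, T =  45, V =  43, W = 130, Y = 107)
)

## Standardize a 20-residue scale to zero mean and unit (population) variance,
## the normalization the pseudo-AAC correlation factors assume.
standardize_scale <- function(x) {
  x <- x[AA]
  (x - mean(x)) / sqrt(mean((x - mean(x))^2))
}

## residue -> group index lookup for a 3-group CTD property
ctd_group_of <- function(property) {
  groups <- CTD_PROPERTIES[[property]]
  g <- integer(20)
  names(g) <- AA
  for (k in 1:3) g[groups[[k]]] <- k
  g
}

gaac_group_of <- function() {
  g <- integer(20)
  names(g) <- AA
  for (k in seq_along(GAAC_GROUPS)) g[GAAC_GROUPS[[k]]] <- k
  g
}

ct_class_of <- function() {
  g <- integer(20)
  names(g) <- AA
  for (k in seq_along(CT_CLASSES)) g[CT_CLASSES[[k]]] <- k
  g
}

#' Residue property tables used by the encoders
#'
#' Returns the fixed lookup tables behind the descriptor families: the
#' 20-letter amino acid alphabet, the 5-group physicochemical partition used
#' by the grouped-composition encoders, the 7-class conjoint-triad partition,
#' the 13 three-group composition/transition/distribution (C/T/D) property
#' partitions, and the three numeric scales (hydrophobicity, hydrophilicity,
#' side-chain mass) used by pseudo amino acid composition.
#'
#' Each partition covers all 20 residues exactly once; each numeric scale is
#' defined for all 20 residues.
#'
#' @return A named list with elements `alphabet`, `gaac_groups`, `ct_classes`,
#'   `ctd_properties`, `paac_scales`.
#' @examples
#' tabs <- property_tables()
#' tabs$gaac_groups$aromatic
#' @export
property_tables <- function() {
  list(
    alphabet = AA,
    gaac_groups = GAAC_GROUPS,
    ct_classes = CT_CLASSES,
    ctd_properties = CTD_PROPERTIES,
    paac_scales = PAAC_SCALES
  )
}
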