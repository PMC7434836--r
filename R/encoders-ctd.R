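#' Conjoint triad encoding (CT)
#'
#' Collapses the 20 residues into 7 classes (\{A,G,V\}, \{I,L,F,P\},
#' \{Y,M,T,S\}, \{H,N,Q,W\}, \{R,K\}, \{D,E\}, \{C\} — the original
#' conjoint-triad partition by side-chain dipole and volume) and counts the
#' `N-2` overlapping class triads, so that triads of class-equivalent
#' residues (e.g. GLM and VFT) map to the same feature. 343 features named
#' `"CT.abc"` with class digits `a`, `b`, `c` in 1..7.
#'
#' @inheritParams kmer_composition
#' @param normalize `"frequency"` (default): raw count divided by `N-2`, so
#'   the vector sums to 1; `"minmax"`: `(count - min(count)) / max(count)`.
#' @examples
#' p <- tibble::tibble(id = "x", sequence = "GAVGAV")
#' enc <- encode_ct(p)
#' enc[["CT.111"]]  # 1: all four triads are class-1 triads
#' @export
encode_ct <- function(peptides, normalize = c("frequency", "minmax")) {
  normalize <- match.arg(normalize)
  check_min_len(peptides, 3, "CT")
  lk <- ct_class_of()
  nms <- paste0("CT.", kmer_names(as.character(1:7), 3))
  encode_tbl(peptides, function(s) {
    codes <- seq_codes(s, lk)
    n <- length(codes)
    cnt <- count_kmers(codes, 3, 7) * (n - 2)  # back to raw counts
    if (normalize == "frequency") cnt / (n - 2)
    else (cnt - min(cnt)) / max(cnt)
  }, nms)
}

ctd_percentiles <- c(0, 25, 50, 75, 100)

#' Composition / Transition / Distribution descriptors (CTDC, CTDT, CTDD)
#'
#' For each of 13 physicochemical properties, residues are partitioned into 3
#' groups and three descriptor sets are computed:
#'
#' * **C** (composition): the fraction of residues in each group — 3 features
#'   per property, named `"property.G1"` .. `"property.G3"`; they sum to 1.
#' * **T** (transition): for each unordered group pair, the number of
#'   adjacent residue pairs whose groups differ in that way (either order),
#'   divided by `N-1` — 3 features per property, named `"property.Tr1221"`,
#'   `"property.Tr1331"`, `"property.Tr2332"`.
#' * **D** (distribution): for each group, the 1-based sequence positions of
#'   the first, 25%, 50%, 75% and 100% occurrences of the group (the
#'   `ceiling(q * n_g)`-th occurrence for quantile `q`, the first occurrence
#'   for `residue0`), each divided by `N` and scaled by 100 — 15 features per
#'   property, named `"property.g.residueP"` with group `g` in 1..3 and `P`
#'   in \{0,25,50,75,100\}. A group with no occurrences yields 0 for all five
#'   descriptors.
#'
#' The 13 properties are seven hydrophobicity scales
#' (`hydrophobicity_PRAM900101` etc.), `normwaalsvolume`, `polarity`,
#' `polarizability`, `charge`, `secondarystruct` and `solventaccess`; see
#' [property_tables()].
#'
#' @inheritParams kmer_composition
#' @param properties Character vector of property names (default: all 13).
#' @examples
#' p <- tibble::tibble(id = "h", sequence = "AAAAA")
#' all(encode_ctdt(p)[, -1] == 0)  # homopolymer: no transitions
#' @name ctd
NULL

#' @rdname ctd
#' @export
encode_ctdc <- function(peptides, properties = names(CTD_PROPERTIES)) {
  check_ctd_properties(properties)
  check_min_len(peptides, 1, "CTDC")
  nms <- unlist(lapply(properties, function(p) paste0(p, ".G", 1:3)))
  lks <- lapply(properties, ctd_group_of)
  encode_tbl(peptides, function(s) {
    codes <- seq_codes(s)
    unlist(lapply(lks, function(lk) tabulate(lk[codes], 3) / length(codes)))
  }, nms)
}

#' @rdname ctd
#' @export
encode_ctdt <- function(peptides, properties = names(CTD_PROPERTIES)) {
  check_ctd_properties(properties)
  check_min_len(peptides, 2, "CTDT")
  nms <- unlist(lapply(properties, function(p)
    paste0(p, c(".Tr1221", ".Tr1331", ".Tr2332"))))
  lks <- lapply(properties, ctd_group_of)
  encode_tbl(peptides, function(s) {
    codes <- seq_codes(s)
    n <- length(codes)
    unlist(lapply(lks, function(lk) {
      g <- lk[codes]
      a <- g[-n]; b <- g[-1]
      c(sum((a == 1 & b == 2) | (a == 2 & b == 1)),
        sum((a == 1 & b == 3) | (a == 3 & b == 1)),
        sum((a == 2 & b == 3) | (a == 3 & b == 2))) / (n - 1)
    }))
  }, nms)
}

#' @rdname ctd
#' @export
encode_ctdd <- function(peptides, properties = names(CTD_PROPERTIES)) {
  check_ctd_properties(properties)
  check_min_len(peptides, 1, "CTDD")
  nms <- unlist(lapply(properties, function(p)
    paste0(p, ".", rep(1:3, each = 5), ".residue",
           rep(ctd_percentiles, times = 3))))
  lks <- lapply(properties, ctd_group_of)
  encode_tbl(peptides, function(s) {
    codes <- seq_codes(s)
    n <- length(codes)
    unlist(lapply(lks, function(lk) {
      g <- lk[codes]
      unlist(lapply(1:3, function(k) {
        pos <- which(g == k)
        if (!length(pos)) return(numeric(5))
        idx <- pmax(1L, ceiling(ctd_percentiles / 100 * length(pos)))
        pos[idx] / n * 100
      }))
    }))
  }, nms)
}

check_ctd_properties <- function(properties) {
  unknown <- setdiff(properties, names(CTD_PROPERTIES))
  if (length(unknown)) {
    stop("unknown C/T/D propert", if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!length(properties)) stop("no C/T/D properties requested", call. = FALSE)
}
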