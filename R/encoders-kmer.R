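## Shared machinery for the composition (k-mer) encoder families.

seq_codes <- function(s, lookup = NULL) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  codes <- match(ch, AA)
  if (anyNA(codes)) {
    stop("sequence contains residue(s) outside the amino acid alphabet: ",
         paste(unique(ch[is.na(codes)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(lookup)) codes else lookup[codes]
}

## lexicographic k-mer names over an ordered alphabet, first position major
kmer_names <- function(alphabet, k, sep = "") {
  grids <- rev(replicate(k, alphabet, simplify = FALSE))
  g <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  apply(g[, rev(seq_len(k)), drop = FALSE], 1, paste, collapse = sep)
}

## counts of consecutive k-mers over codes in 1..m, normalized by N-k+1
count_kmers <- function(codes, k, m) {
  n <- length(codes)
  idx <- codes[seq_len(n - k + 1)]
  if (k >= 2) for (j in 2:k) {
    idx <- (idx - 1L) * m + codes[j:(n - k + j)]
  }
  tabulate(idx, nbins = m^k) / (n - k + 1)
}

## counts of pairs (i, i+gap+1) over codes in 1..m, normalized by N-gap-1
count_gapped_pairs <- function(codes, gap, m) {
  n <- length(codes)
  a <- codes[seq_len(n - gap - 1)]
  b <- codes[(gap + 2):n]
  tabulate((a - 1L) * m + b, nbins = m * m) / (n - gap - 1)
}

check_min_len <- function(peptides, min_len, scheme) {
  n <- nchar(peptides$sequence)
  short <- n < min_len
  if (any(short)) {
    stop(scheme, " requires sequences of length >= ", min_len,
         "; too short: ", paste(peptides$id[short], collapse = ", "),
         call. = FALSE)
  }
}

## Apply a per-sequence encoder over a peptide table, keeping id (and label).
encode_tbl <- function(peptides, fun, feature_names) {
  stopifnot(is.data.frame(peptides),
            all(c("id", "sequence") %in% names(peptides)))
  mat <- vapply(peptides$sequence, fun, numeric(length(feature_names)),
                USE.NAMES = FALSE)
  mat <- matrix(mat, ncol = length(feature_names), byrow = TRUE,
                dimnames = list(NULL, feature_names))
  out <- dplyr::bind_cols(tibble::tibble(id = peptides$id),
                          tibble::as_tibble(mat))
  if ("label" %in% names(peptides)) out$label <- peptides$label
  out
}

#' Amino acid, dipeptide and tripeptide composition (AAC / DPC / TPC)
#'
#' Frequency vectors of single residues, adjacent residue pairs and adjacent
#' residue triples. For a sequence of length `N`, AAC features are counts
#' divided by `N` (20 features), DPC counts of the `N-1` adjacent pairs
#' divided by `N-1` (400 features), and TPC counts of the `N-2` overlapping
#' triples divided by `N-2` (8000 features). Feature names are the k-mers
#' themselves in lexicographic order (`A`..`Y`, `AA`..`YY`, `AAA`..`YYY`).
#' Each vector sums to 1.
#'
#' @param peptides A peptide tibble with columns `id`, `sequence` (and
#'   optionally `label`, carried through).
#' @return A tibble: `id`, one numeric column per feature, and `label` if
#'   present in the input.
#' @examples
#' p <- tibble::tibble(id = "ex", sequence = "CRACRKDSMVN")
#' enc <- encode_aac(p)
#' enc$C  # 2/11
#' @name kmer_composition
NULL

#' @rdname kmer_composition
#' @export
encode_aac <- function(peptides) {
  check_min_len(peptides, 1, "AAC")
  encode_tbl(peptides, function(s) count_kmers(seq_codes(s), 1, 20), AA)
}

#' @rdname kmer_composition
#' @export
encode_dpc <- function(peptides) {
  check_min_len(peptides, 2, "DPC")
  encode_tbl(peptides, function(s) count_kmers(seq_codes(s), 2, 20),
             kmer_names(AA, 2))
}

#' @rdname kmer_composition
#' @export
encode_tpc <- function(peptides) {
  check_min_len(peptides, 3, "TPC")
  encode_tbl(peptides, function(s) count_kmers(seq_codes(s), 3, 20),
             kmer_names(AA, 3))
}

#' k-spaced amino acid pair composition (CKSAAP)
#'
#' For each gap value `k = 0..kmax`, counts ordered residue pairs separated
#' by exactly `k` intervening residues: feature `(a,b)` at gap `k` is the
#' number of positions `i` with `p[i] = a` and `p[i+k+1] = b`, divided by
#' `N-k-1`. Gap 0 is the dipeptide composition. 400 features per gap block,
#' `400 * (kmax+1)` in total, named `"AB.gapk"`; each gap block sums to 1.
#'
#' @inheritParams kmer_composition
#' @param kmax Largest gap (default 5). Sequences must have length
#'   `>= kmax + 2`.
#' @examples
#' p <- tibble::tibble(id = "ex", sequence = "CRACRKDSMVN")
#' enc <- encode_cksaap(p, kmax = 0)
#' enc[["CR.gap0"]]  # 2/10
#' enc[["AC.gap0"]]  # 1/10
#' @export
encode_cksaap <- function(peptides, kmax = 5L) {
  stopifnot(kmax >= 0)
  check_min_len(peptides, kmax + 2, sprintf("CKSAAP (kmax=%d)", kmax))
  nms <- unlist(lapply(0:kmax, function(k) paste0(kmer_names(AA, 2), ".gap", k)))
  encode_tbl(peptides, function(s) {
    codes <- seq_codes(s)
    unlist(lapply(0:kmax, function(k) count_gapped_pairs(codes, k, 20)))
  }, nms)
}

group_names <- function() names(GAAC_GROUPS)

#' Grouped composition family (GAAC / GDPC / GTPC / CKSAAGP)
#'
#' The composition encoders recomputed after collapsing the 20 residues into
#' 5 physicochemical groups: aliphatic \{G,A,V,L,M,I\}, aromatic \{F,Y,W\},
#' positively charged \{K,R,H\}, negatively charged \{D,E\} and uncharged
#' polar \{S,T,C,P,N,Q\}. Dimensions are 5 (GAAC), 25 (GDPC), 125 (GTPC) and
#' `25 * (kmax+1)` (CKSAAGP). Group k-mer names are dot-joined group names
#' (e.g. `"positivecharge.positivecharge"`), CKSAAGP names carry a `.gapk`
#' suffix. The same normalizations and length minima as the ungrouped
#' analogues apply.
#'
#' @inheritParams encode_cksaap
#' @examples
#' p <- tibble::tibble(id = "g", sequence = "GGGG")
#' encode_gaac(p)$aliphatic  # 1
#' @name grouped_composition
NULL

#' @rdname grouped_composition
#' @export
encode_gaac <- function(peptides) {
  check_min_len(peptides, 1, "GAAC")
  lk <- gaac_group_of()
  encode_tbl(peptides, function(s) count_kmers(seq_codes(s, lk), 1, 5),
             group_names())
}

#' @rdname grouped_composition
#' @export
encode_gdpc <- function(peptides) {
  check_min_len(peptides, 2, "GDPC")
  lk <- gaac_group_of()
  encode_tbl(peptides, function(s) count_kmers(seq_codes(s, lk), 2, 5),
             kmer_names(group_names(), 2, sep = "."))
}

#' @rdname grouped_composition
#' @export
encode_gtpc <- function(peptides) {
  check_min_len(peptides, 3, "GTPC")
  lk <- gaac_group_of()
  encode_tbl(peptides, function(s) count_kmers(seq_codes(s, lk), 3, 5),
             kmer_names(group_names(), 3, sep = "."))
}

#' @rdname grouped_composition
#' @export
encode_cksaagp <- function(peptides, kmax = 5L) {
  stopifnot(kmax >= 0)
  check_min_len(peptides, kmax + 2, sprintf("CKSAAGP (kmax=%d)", kmax))
  lk <- gaac_group_of()
  nms <- unlist(lapply(0:kmax, function(k)
    paste0(kmer_names(group_names(), 2, sep = "."), ".gap", k)))
  encode_tbl(peptides, function(s) {
    codes <- seq_codes(s, lk)
    unlist(lapply(0:kmax, function(k) count_gapped_pairs(codes, k, 5)))
  }, nms)
}
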