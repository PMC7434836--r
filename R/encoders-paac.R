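#' Pseudo and amphiphilic pseudo amino acid composition (PAAC / APAAC)
#'
#' Augments the amino acid composition with `lambda` sequence-order
#' correlation terms built from physicochemical scales (hydrophobicity,
#' hydrophilicity, side-chain mass; standardized to zero mean and unit
#' variance over the 20 residues before use).
#'
#' **PAAC** (dimension `20 + lambda`): the order factor for tier `j` is
#' \deqn{\theta_j = \frac{1}{N-j} \sum_{i=1}^{N-j} \Theta(R_i, R_{i+j}),}
#' where \eqn{\Theta(a,b)} is the mean over the three scales of the squared
#' scale difference between residues `a` and `b`. With residue frequencies
#' `f_a` (summing to 1) and weight `w`, the composition part is
#' `Xc1.a = f_a / (1 + w * sum(theta))` and the order part
#' `Xc2.lambda.j = w * theta_j / (1 + w * sum(theta))`.
#'
#' **APAAC** (dimension `20 + 2*lambda`) keeps the hydrophobicity and
#' hydrophilicity scales separate: for each tier `j` and scale `u`,
#' `tau_{j,u}` is the mean product of the standardized scale values of
#' residues `j` apart; features are `Pc1.a` (composition) and
#' `Pc2.<Scale>.j` (order), with the same denominator structure.
#'
#' At `lambda = 0`, or at `w = 0` for the composition part, both reduce
#' exactly to the amino acid composition.
#'
#' @inheritParams kmer_composition
#' @param lambda Number of sequence-order correlation tiers (default 8).
#'   Sequences must have length `>= lambda + 1`.
#' @param w Weight of the order terms (default 0.05).
#' @examples
#' p <- tibble::tibble(id = "a10", sequence = "AAAAAAAAAA")
#' encode_paac(p, lambda = 1)[["Xc1.A"]]  # 1: identical residues, theta = 0
#' @name paac
NULL

paac_theta <- function(codes, lambda, scales) {
  n <- length(codes)
  vapply(seq_len(lambda), function(j) {
    i <- seq_len(n - j)
    mean(vapply(scales, function(h) mean((h[codes[i + j]] - h[codes[i]])^2),
                numeric(1)))
  }, numeric(1))
}

#' @rdname paac
#' @export
encode_paac <- function(peptides, lambda = 8L, w = 0.05) {
  stopifnot(lambda >= 0, w >= 0)
  check_min_len(peptides, lambda + 1, sprintf("PAAC (lambda=%d)", lambda))
  scales <- lapply(PAAC_SCALES, standardize_scale)
  nms <- c(paste0("Xc1.", AA),
           if (lambda > 0) paste0("Xc2.lambda.", seq_len(lambda)))
  encode_tbl(peptides, function(s) {
    codes <- seq_codes(s)
    f <- tabulate(codes, 20) / length(codes)
    theta <- if (lambda > 0) paac_theta(codes, lambda, scales) else numeric(0)
    denom <- 1 + w * sum(theta)
    c(f / denom, w * theta / denom)
  }, nms)
}

#' @rdname paac
#' @export
encode_apaac <- function(peptides, lambda = 8L, w = 0.05) {
  stopifnot(lambda >= 0, w >= 0)
  check_min_len(peptides, lambda + 1, sprintf("APAAC (lambda=%d)", lambda))
  scales <- lapply(PAAC_SCALES[c("Hydrophobicity", "Hydrophilicity")],
                   standardize_scale)
  nms <- c(paste0("Pc1.", AA),
           if (lambda > 0)
             paste0("Pc2.", rep(names(scales), times = lambda), ".",
                    rep(seq_len(lambda), each = 2)))
  encode_tbl(peptides, function(s) {
    codes <- seq_codes(s)
    n <- length(codes)
    f <- tabulate(codes, 20) / n
    tau <- if (lambda > 0) unlist(lapply(seq_len(lambda), function(j) {
      i <- seq_len(n - j)
      vapply(scales, function(h) mean(h[codes[i]] * h[codes[i + j]]),
             numeric(1))
    })) else numeric(0)
    denom <- 1 + w * sum(tau)
    c(f / denom, w * tau / denom)
  }, nms)
}
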