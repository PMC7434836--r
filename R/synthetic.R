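#' Simulate a labeled peptide dataset with a planted composition bias
#'
#' Generates short peptides (lengths uniform over `length_range`, default
#' 5-30 residues — the typical anticancer peptide length range) with
#' residues sampled independently. Negative-class residues are uniform over
#' the 20 amino acids. Positive-class residues are drawn from a mixture of
#' that uniform background and a designated tilt set (default
#' \{K, R, L, G, C\}, echoing the residues whose composition and content
#' discriminate anticancer peptides): residue `r` has probability
#' \deqn{p_r = \frac{1/20 + b\,[r \in T]/|T|}{1 + b}}
#' for bias `b` and tilt set `T`, so `bias = 0` makes the classes
#' exchangeable and larger bias concentrates positive-class mass on the tilt
#' residues. The default class sizes mirror the 138:206 benchmark imbalance.
#'
#' With `motif = TRUE`, each positive peptide additionally receives a
#' planted gapped residue pair (default `G` then `L` separated by
#' `motif_gap = 4` intervening residues) at a random feasible position — a
#' positional signal for exercising the k-spaced pair encoders, which pure
#' composition bias cannot.
#'
#' Everything is reproducible from `seed`.
#'
#' @param n_pos,n_neg Class sizes (defaults 138 and 206).
#' @param length_range Integer min/max peptide length (default `c(5, 30)`).
#' @param bias Non-negative tilt strength (default 1).
#' @param tilt_set Residues favored in the positive class.
#' @param motif Plant a gapped residue pair in positives (default `FALSE`).
#' @param motif_pair,motif_gap The planted pair and its gap.
#' @param seed Integer seed.
#' @return A labeled peptide tibble: `id`, `description`, `sequence`,
#'   `label` (1 for the `n_pos` positives, then 0 for the negatives).
#' @examples
#' d <- simulate_peptides(n_pos = 5, n_neg = 5, bias = 2, seed = 1)
#' d$sequence
#' @export
simulate_peptides <- function(n_pos = 138L, n_neg = 206L,
                              length_range = c(5L, 30L), bias = 1,
                              tilt_set = c("K", "R", "L", "G", "C"),
                              motif = FALSE, motif_pair = c("G", "L"),
                              motif_gap = 4L, seed = 1L) {
  stopifnot(n_pos + n_neg >= 2, bias >= 0, length(length_range) == 2)
  if (length_range[1] > length_range[2] || length_range[1] < 1) {
    stop("invalid length range", call. = FALSE)
  }
  if (!all(tilt_set %in% AA)) stop("tilt_set outside the alphabet", call. = FALSE)
  if (motif) {
    stopifnot(all(motif_pair %in% AA), motif_gap >= 0)
    if (length_range[1] < motif_gap + 2) {
      stop("length range too short for the planted motif gap", call. = FALSE)
    }
  }
  p_bg <- stats::setNames(rep(1 / 20, 20), AA)
  p_pos <- (p_bg + bias * (AA %in% tilt_set) / length(tilt_set)) / (1 + bias)
  withr::with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_pos + n_neg,
                   replace = TRUE)
    seqs <- vapply(seq_len(n_pos + n_neg), function(i) {
      p <- if (i <= n_pos) p_pos else p_bg
      s <- sample(AA, lens[i], replace = TRUE, prob = p)
      if (motif && i <= n_pos) {
        start <- sample.int(lens[i] - motif_gap - 1, 1)
        s[start] <- motif_pair[1]
        s[start + motif_gap + 1] <- motif_pair[2]
      }
      paste(s, collapse = "")
    }, character(1))
  })
  tibble::tibble(
    id = c(sprintf("pos%04d", seq_len(n_pos)),
           sprintf("neg%04d", seq_len(n_neg))),
    description = "",
    sequence = seqs,
    label = rep(c(1L, 0L), c(n_pos, n_neg))
  )
}

#' Ground-truth informative features of a simulated dataset
#'
#' For a positive `bias`, the planted signal lives in the amino acid
#' composition of the tilt residues; this returns those AAC feature names
#' (which in the feature-name grammar are the residue letters themselves),
#' the ground truth for selection-recovery experiments. With `motif = TRUE`
#' the planted k-spaced pair feature (e.g. `"GL.gap4"`) is included.
#'
#' @inheritParams simulate_peptides
#' @return Character vector of feature names.
#' @examples
#' planted_truth(bias = 2)  # "K" "R" "L" "G" "C"
#' @export
planted_truth <- function(bias = 1, tilt_set = c("K", "R", "L", "G", "C"),
                          motif = FALSE, motif_pair = c("G", "L"),
                          motif_gap = 4L) {
  if (bias <= 0 && !motif) {
    stop("bias = 0 plants no signal: no ground-truth features exist",
         call. = FALSE)
  }
  out <- if (bias > 0) tilt_set else character(0)
  if (motif) {
    out <- c(out, paste0(motif_pair[1], motif_pair[2], ".gap", motif_gap))
  }
  out
}

#' Append uninformative noise features to a feature table
#'
#' Adds `n_noise` iid standard-normal feature columns (named `"noise.001"`,
#' ...) to a feature tibble — label-independent distractors for
#' feature-selection recovery experiments.
#'
#' @param data A feature tibble.
#' @param n_noise Number of noise columns (default 100).
#' @param seed Integer seed.
#' @return `data` with the noise columns appended before any `label`
#'   column.
#' @export
add_noise_features <- function(data, n_noise = 100L, seed = 1L) {
  stopifnot(is.data.frame(data), n_noise >= 1)
  noise <- withr::with_seed(seed,
    matrix(stats::rnorm(nrow(data) * n_noise), nrow = nrow(data)))
  colnames(noise) <- sprintf("noise.%03d", seq_len(n_noise))
  out <- dplyr::bind_cols(
    dplyr::select(data, -dplyr::any_of("label")),
    tibble::as_tibble(noise))
  if ("label" %in% names(data)) out$label <- data$label
  out
}

#' Write a simulated dataset in the two-FASTA benchmark layout
#'
#' Splits a labeled peptide tibble into a positives FASTA and a negatives
#' FASTA, the layout [load_labeled()] consumes.
#'
#' @param data A labeled peptide tibble.
#' @param pos_path,neg_path Output FASTA paths.
#' @return Invisibly, `c(pos_path, neg_path)`.
#' @export
write_two_fasta <- function(data, pos_path, neg_path) {
  stopifnot(all(c("id", "sequence", "label") %in% names(data)))
  write_fasta(dplyr::filter(data, .data$label == 1L), pos_path)
  write_fasta(dplyr::filter(data, .data$label == 0L), neg_path)
  invisible(c(pos_path, neg_path))
}
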