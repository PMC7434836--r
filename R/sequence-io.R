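#' Read peptide sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) FASTA file of peptide sequences and returns
#' a validated peptide table. The record id is the header token up to the
#' first whitespace; the remainder of the header line is kept as the
#' `description`. Every residue must belong to the 20-letter standard amino
#' acid alphabet; nonstandard residues (X, B, Z, U, O, gap characters, ...)
#' are rejected with an error naming the record and the offending character —
#' they are never silently dropped, because the composition encoders'
#' denominators assume every residue is counted. With `drop_invalid = TRUE`
#' whole offending records are excluded with a warning (never single
#' residues).
#'
#' @param path Path to a FASTA file.
#' @param uppercase Fold lowercase residues to uppercase before validation
#'   (default `TRUE`).
#' @param drop_invalid Drop records containing nonstandard residues with a
#'   warning instead of erroring (default `FALSE`).
#' @return A tibble with columns `id`, `description`, `sequence`, one row per
#'   record in file order. Ids must be unique within the file.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 example", "GLFDIIK", ">p2", "ACDEF"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, uppercase = TRUE, drop_invalid = FALSE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  check_fasta_format(path)
  set <- Biostrings::readBStringSet(path)
  headers <- as.character(names(set))
  ids <- sub("\\s.*$", "", headers)
  desc <- as.character(ifelse(grepl("\\s", headers),
                              sub("^\\S+\\s+", "", headers), ""))
  seqs <- unname(as.character(set))
  if (uppercase) seqs <- toupper(seqs)
  tbl <- tibble::tibble(id = ids, description = desc, sequence = seqs)
  if (length(ids) && anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !purrr::map_lgl(tbl$sequence, sequence_is_valid)
  if (any(bad)) {
    if (drop_invalid) {
      warning(sum(bad), " record(s) with nonstandard residues dropped: ",
              paste(tbl$id[bad], collapse = ", "), call. = FALSE)
      tbl <- tbl[!bad, ]
    } else {
      first <- which(bad)[1]
      offending <- setdiff(strsplit(tbl$sequence[first], "")[[1]], AA)
      stop("record '", tbl$id[first], "' contains residue(s) outside the ",
           "20-letter amino acid alphabet: ",
           paste(unique(offending), collapse = ", "),
           if (sum(bad) > 1) paste0(" (and ", sum(bad) - 1, " more record(s))"),
           call. = FALSE)
    }
  }
  empty <- !nzchar(tbl$sequence)
  if (any(empty)) {
    stop("record '", tbl$id[which(empty)[1]], "' has an empty sequence",
         call. = FALSE)
  }
  tbl
}

## Cheap structural pre-check so malformed input fails with a line number
## rather than an opaque parser error.
check_fasta_format <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(invisible(TRUE))
  first <- nonblank[1]
  if (!startsWith(lines[first], ">")) {
    stop("malformed FASTA at line ", first,
         ": expected a '>' header before sequence data", call. = FALSE)
  }
  hdr <- which(startsWith(lines, ">"))
  empty_hdr <- hdr[!nzchar(sub("^>\\s*", "", lines[hdr]))]
  if (length(empty_hdr)) {
    stop("malformed FASTA at line ", empty_hdr[1], ": empty header",
         call. = FALSE)
  }
  invisible(TRUE)
}

sequence_is_valid <- function(s) {
  nchar(s) >= 1 && !grepl(paste0("[^", paste(AA, collapse = ""), "]"), s)
}

#' Write peptides to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` reproduces `x`
#' for validated peptides.
#'
#' @param peptides A peptide tibble with columns `id`, `sequence` and
#'   optionally `description`.
#' @param path Output file path.
#' @param width Line-wrap width for sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(peptides, path, width = 60L) {
  stopifnot(is.data.frame(peptides), all(c("id", "sequence") %in% names(peptides)))
  desc <- if ("description" %in% names(peptides)) peptides$description else ""
  hdr <- ifelse(nzchar(desc), paste(peptides$id, desc), peptides$id)
  set <- Biostrings::BStringSet(peptides$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Load a labeled peptide dataset from two FASTA files
#'
#' Reads positives (anticancer peptides, label 1) and negatives (label 0)
#' from separate FASTA files — the standard two-file benchmark layout — and
#' binds them into one labeled dataset. Ids must not overlap between the two
#' files. An empty class is allowed with a warning (some operations
#' downstream will refuse single-class data themselves).
#'
#' @param pos_path FASTA file of positive-class peptides (label 1).
#' @param neg_path FASTA file of negative-class peptides (label 0).
#' @inheritParams read_fasta
#' @return A tibble with columns `id`, `description`, `sequence`, `label`
#'   (integer 0/1), positives first.
#' @examples
#' pos <- tempfile(fileext = ".fasta"); neg <- tempfile(fileext = ".fasta")
#' writeLines(c(">a1", "KLWKKLL", ">a2", "GLLKRIK"), pos)
#' writeLines(c(">n1", "ASDTPN", ">n2", "QQEDST", ">n3", "MNPQRS"), neg)
#' load_labeled(pos, neg)
#' @export
load_labeled <- function(pos_path, neg_path, uppercase = TRUE,
                         drop_invalid = FALSE) {
  pos <- read_fasta(pos_path, uppercase = uppercase, drop_invalid = drop_invalid)
  neg <- read_fasta(neg_path, uppercase = uppercase, drop_invalid = drop_invalid)
  overlap <- intersect(pos$id, neg$id)
  if (length(overlap)) {
    stop("id(s) present in both the positive and negative files: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  if (nrow(pos) == 0) warning("positive class is empty", call. = FALSE)
  if (nrow(neg) == 0) warning("negative class is empty", call. = FALSE)
  dplyr::bind_rows(
    dplyr::mutate(pos, label = 1L),
    dplyr::mutate(neg, label = 0L)
  )
}

#' Write a feature table to TSV or CSV
#'
#' Writes an encoded feature table (first column `id`, then one column per
#' structured feature name, plus `label` if present) to a delimited text
#' file. The header row carries the rendered feature names, so the table can
#' be re-read and its columns resolved with [resolve_feature()].
#'
#' @param features A feature tibble as returned by the `encode_*` functions.
#' @param path Output path; a `.csv` extension selects comma separation,
#'   anything else tab separation.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.data.frame(features))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(features, path)
  } else {
    readr::write_tsv(features, path)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Path to a TSV/CSV feature table with an `id` first column.
#' @return A tibble.
#' @export
read_feature_table <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, comment = "#")
  } else {
    readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  }
}
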