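## Feature-name grammar (version 1, case-sensitive). One production per
## encoder family; render and parse are mutual inverses.
##
##   AAC      A                        single residue letter
##   DPC      AC                       residue pair
##   TPC      ACD                      residue triple
##   CKSAAP   AC.gap4                  residue pair + gap
##   GAAC     aliphatic                group name
##   GDPC     aliphatic.aromatic       group pair
##   GTPC     g.g.g                    group triple
##   CKSAAGP  aliphatic.aromatic.gap2  group pair + gap
##   CT       CT.125                   class digits in 1..7
##   CTDC     polarity.G2              property + group
##   CTDT     polarity.Tr1221          property + unordered group pair
##   CTDD     polarizability.2.residue0  property + group + percentile
##   PAAC     Xc1.K | Xc2.lambda.3     composition | order tier
##   APAAC    Pc1.C | Pc2.Hydrophobicity.8

aa_re <- function() paste0("[", paste(AA, collapse = ""), "]")
grp_re <- function() paste0("(", paste(names(GAAC_GROUPS), collapse = "|"), ")")
prop_re <- function() paste0("(", paste(names(CTD_PROPERTIES), collapse = "|"), ")")

#' Resolve a structured feature name to its encoder and parameters
#'
#' Parses a rendered feature name back into the encoder that produces it,
#' the encoder-specific components, and the column index within that
#' encoder's full output — enough information to compute that single feature
#' for any peptide. Parsing is case-sensitive and is the exact inverse of
#' the rendering used by the `encode_*` functions.
#'
#' @param name A single feature name, e.g. `"GL.gap4"`, `"Xc1.K"`,
#'   `"polarizability.2.residue0"`.
#' @return A list with elements `name`, `encoder` (one of AAC, DPC, TPC,
#'   CKSAAP, GAAC, GDPC, GTPC, CKSAAGP, CT, CTDC, CTDT, CTDD, PAAC, APAAC),
#'   `params` (named list of parsed components) and `index` (column position
#'   in the generating encoder's full output, for that encoder's minimal
#'   parameters).
#' @examples
#' resolve_feature("GL.gap4")$encoder   # "CKSAAP"
#' resolve_feature("Xc1.K")$params$residue
#' @export
resolve_feature <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  a <- aa_re(); g <- grp_re(); p <- prop_re()
  res <- function(encoder, params, index)
    list(name = name, encoder = encoder, params = params, index = index)
  gi <- function(x) match(x, names(GAAC_GROUPS))
  ai <- function(x) match(x, AA)

  if (grepl(paste0("^", a, "$"), name)) {
    return(res("AAC", list(residue = name), ai(name)))
  }
  if (grepl(paste0("^", a, a, "$"), name)) {
    r <- strsplit(name, "")[[1]]
    return(res("DPC", list(pair = r), (ai(r[1]) - 1L) * 20L + ai(r[2])))
  }
  if (grepl(paste0("^", a, a, a, "$"), name)) {
    r <- strsplit(name, "")[[1]]
    return(res("TPC", list(triple = r),
               (ai(r[1]) - 1L) * 400L + (ai(r[2]) - 1L) * 20L + ai(r[3])))
  }
  m <- regmatches(name, regexec(paste0("^(", a, ")(", a, ")\\.gap([0-9]+)$"), name))[[1]]
  if (length(m)) {
    k <- as.integer(m[4])
    return(res("CKSAAP", list(pair = c(m[2], m[3]), gap = k),
               k * 400L + (ai(m[2]) - 1L) * 20L + ai(m[3])))
  }
  if (name %in% names(GAAC_GROUPS)) {
    return(res("GAAC", list(group = name), gi(name)))
  }
  m <- regmatches(name, regexec(paste0("^", g, "\\.", g, "\\.gap([0-9]+)$"), name))[[1]]
  if (length(m)) {
    k <- as.integer(m[4])
    return(res("CKSAAGP", list(pair = c(m[2], m[3]), gap = k),
               k * 25L + (gi(m[2]) - 1L) * 5L + gi(m[3])))
  }
  m <- regmatches(name, regexec(paste0("^", g, "\\.", g, "$"), name))[[1]]
  if (length(m)) {
    return(res("GDPC", list(pair = c(m[2], m[3])),
               (gi(m[2]) - 1L) * 5L + gi(m[3])))
  }
  m <- regmatches(name, regexec(paste0("^", g, "\\.", g, "\\.", g, "$"), name))[[1]]
  if (length(m)) {
    return(res("GTPC", list(triple = c(m[2], m[3], m[4])),
               (gi(m[2]) - 1L) * 25L + (gi(m[3]) - 1L) * 5L + gi(m[4])))
  }
  m <- regmatches(name, regexec("^CT\\.([1-7])([1-7])([1-7])$", name))[[1]]
  if (length(m)) {
    cl <- as.integer(m[2:4])
    return(res("CT", list(classes = cl),
               (cl[1] - 1L) * 49L + (cl[2] - 1L) * 7L + cl[3]))
  }
  m <- regmatches(name, regexec(paste0("^", p, "\\.G([123])$"), name))[[1]]
  if (length(m)) {
    return(res("CTDC", list(property = m[2], group = as.integer(m[3])),
               (match(m[2], names(CTD_PROPERTIES)) - 1L) * 3L + as.integer(m[3])))
  }
  m <- regmatches(name, regexec(paste0("^", p, "\\.Tr(1221|1331|2332)$"), name))[[1]]
  if (length(m)) {
    tr <- match(m[3], c("1221", "1331", "2332"))
    return(res("CTDT", list(property = m[2], transition = m[3]),
               (match(m[2], names(CTD_PROPERTIES)) - 1L) * 3L + tr))
  }
  m <- regmatches(name, regexec(paste0("^", p, "\\.([123])\\.residue(0|25|50|75|100)$"), name))[[1]]
  if (length(m)) {
    grp <- as.integer(m[3])
    pct <- match(as.integer(m[4]), ctd_percentiles)
    return(res("CTDD",
               list(property = m[2], group = grp, percentile = as.integer(m[4])),
               (match(m[2], names(CTD_PROPERTIES)) - 1L) * 15L +
                 (grp - 1L) * 5L + pct))
  }
  m <- regmatches(name, regexec(paste0("^Xc1\\.(", a, ")$"), name))[[1]]
  if (length(m)) {
    return(res("PAAC", list(part = "composition", residue = m[2]), ai(m[2])))
  }
  m <- regmatches(name, regexec("^Xc2\\.lambda\\.([0-9]+)$", name))[[1]]
  if (length(m)) {
    j <- as.integer(m[2])
    if (j < 1) stop("invalid order tier in '", name, "'", call. = FALSE)
    return(res("PAAC", list(part = "order", tier = j), 20L + j))
  }
  m <- regmatches(name, regexec(paste0("^Pc1\\.(", a, ")$"), name))[[1]]
  if (length(m)) {
    return(res("APAAC", list(part = "composition", residue = m[2]), ai(m[2])))
  }
  m <- regmatches(name, regexec("^Pc2\\.(Hydrophobicity|Hydrophilicity)\\.([0-9]+)$", name))[[1]]
  if (length(m)) {
    j <- as.integer(m[3])
    if (j < 1) stop("invalid order tier in '", name, "'", call. = FALSE)
    return(res("APAAC", list(part = "order", scale = m[2], tier = j),
               20L + (j - 1L) * 2L + match(m[2], c("Hydrophobicity", "Hydrophilicity"))))
  }
  stop("cannot resolve feature name '", name, "'; expected one of: ",
       "residue k-mers (A, AC, ACD), 'AB.gapK' (CKSAAP), group names and ",
       "group k-mers (GAAC family), 'CT.abc', '<property>.G1/.TrXXXX/",
       ".<g>.residueP' (C/T/D), 'Xc1.<res>'/'Xc2.lambda.<j>' (PAAC), ",
       "'Pc1.<res>'/'Pc2.<Scale>.<j>' (APAAC)", call. = FALSE)
}

## Minimal encoder call covering a set of resolved names of one encoder.
encoder_call <- function(encoder, resolved, peptides, kmax, lambda, w) {
  switch(encoder,
    AAC = encode_aac(peptides),
    DPC = encode_dpc(peptides),
    TPC = encode_tpc(peptides),
    GAAC = encode_gaac(peptides),
    GDPC = encode_gdpc(peptides),
    GTPC = encode_gtpc(peptides),
    CT = encode_ct(peptides),
    CTDC = encode_ctdc(peptides),
    CTDT = encode_ctdt(peptides),
    CTDD = encode_ctdd(peptides),
    CKSAAP = encode_cksaap(peptides, kmax = max(
      kmax, vapply(resolved, function(r) as.numeric(r$params$gap), numeric(1)))),
    CKSAAGP = encode_cksaagp(peptides, kmax = max(
      kmax, vapply(resolved, function(r) as.numeric(r$params$gap), numeric(1)))),
    PAAC = encode_paac(peptides, lambda = max(lambda, unlist(
      lapply(resolved, function(r) r$params$tier))), w = w),
    APAAC = encode_apaac(peptides, lambda = max(lambda, unlist(
      lapply(resolved, function(r) r$params$tier))), w = w),
    stop("unknown encoder: ", encoder, call. = FALSE)
  )
}

#' Encode only a named set of features
#'
#' Computes exactly the requested features (in the requested column order)
#' for a peptide table, resolving each structured name to its generating
#' encoder. This is how a low-dimensional model manifest (e.g. the shipped
#' seven-feature manifest, see [model_7d_manifest()]) is applied to new
#' peptides.
#'
#' @inheritParams kmer_composition
#' @param names Character vector of feature names; every name must conform
#'   to the feature-name grammar (see [resolve_feature()]).
#' @param kmax,lambda,w Encoder parameters used when computing the requested
#'   features. `kmax` and `lambda` are floors, raised automatically when a
#'   requested name requires more (e.g. `"GL.gap4"` forces `kmax >= 4`,
#'   `"Pc2.Hydrophobicity.8"` forces `lambda >= 8`). `lambda` defaults to
#'   the package-wide pseudo-AAC default 8 so a bare composition name like
#'   `"Xc1.K"` gets the same value as in the full default [encode_paac()]
#'   output; pass `lambda = 0` for short peptides if no order-tier feature
#'   is requested.
#' @return A tibble `id`, one column per requested name (plus `label` if
#'   present in the input). Encoder length preconditions apply to every
#'   sequence and failures name the offending peptide ids.
#' @examples
#' p <- tibble::tibble(id = "s", sequence = "GLWSKIKEVGKEAAKAAAKA")
#' encode_selected(p, c("Xc1.K", "GL.gap4"))
#' @export
encode_selected <- function(peptides, names, kmax = 0L, lambda = 8L, w = 0.05) {
  stopifnot(is.character(names))
  out <- tibble::tibble(id = peptides$id)
  if (length(names)) {
    resolved <- lapply(names, resolve_feature)
    enc <- vapply(resolved, `[[`, character(1), "encoder")
    cols <- vector("list", length(names))
    for (e in unique(enc)) {
      sel <- which(enc == e)
      full <- encoder_call(e, resolved[sel], peptides, kmax, lambda, w)
      missing <- setdiff(names[sel], colnames(full))
      if (length(missing)) {
        stop("feature(s) not produced by ", e, ": ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      for (i in sel) cols[[i]] <- full[[names[i]]]
    }
    names(cols) <- names
    out <- dplyr::bind_cols(out, tibble::as_tibble(cols))
  }
  if ("label" %in% colnames(peptides)) out$label <- peptides$label
  out
}

ENCODER_REGISTRY <- c("AAC", "CKSAAP", "DPC", "TPC", "CT", "CTDC", "CTDT",
                      "CTDD", "PAAC", "APAAC", "GAAC", "CKSAAGP", "GDPC",
                      "GTPC")

#' Encode peptides with one or more descriptor families
#'
#' Dispatcher over the twelve descriptor families. Feature columns of the
#' selected encoders are bound side by side in the order given.
#'
#' @inheritParams kmer_composition
#' @param encoders Character vector of encoder ids among AAC, CKSAAP, DPC,
#'   TPC, CT, CTDC, CTDT, CTDD, PAAC, APAAC, GAAC, CKSAAGP, GDPC, GTPC.
#' @param kmax Gap maximum for CKSAAP/CKSAAGP (default 5).
#' @param lambda,w Pseudo-AAC parameters (defaults 8 and 0.05).
#' @param ct_normalize Conjoint-triad normalization, see [encode_ct()].
#' @return A tibble `id`, feature columns, and `label` if present.
#' @examples
#' p <- tibble::tibble(id = c("a", "b"),
#'                     sequence = c("KLWKKLLKKWLKG", "ASDTPNQEDSTMNP"))
#' dim(encode_features(p, c("AAC", "GAAC")))  # 2 x 26
#' @export
encode_features <- function(peptides, encoders = "AAC", kmax = 5L,
                            lambda = 8L, w = 0.05,
                            ct_normalize = c("frequency", "minmax")) {
  encoders <- match.arg(encoders, ENCODER_REGISTRY, several.ok = TRUE)
  ct_normalize <- match.arg(ct_normalize)
  parts <- lapply(encoders, function(e) {
    out <- switch(e,
      AAC = encode_aac(peptides), DPC = encode_dpc(peptides),
      TPC = encode_tpc(peptides), CKSAAP = encode_cksaap(peptides, kmax),
      GAAC = encode_gaac(peptides), GDPC = encode_gdpc(peptides),
      GTPC = encode_gtpc(peptides), CKSAAGP = encode_cksaagp(peptides, kmax),
      CT = encode_ct(peptides, ct_normalize),
      CTDC = encode_ctdc(peptides), CTDT = encode_ctdt(peptides),
      CTDD = encode_ctdd(peptides),
      PAAC = encode_paac(peptides, lambda, w),
      APAAC = encode_apaac(peptides, lambda, w))
    dplyr::select(out, -dplyr::any_of(c("id", "label")))
  })
  out <- dplyr::bind_cols(tibble::tibble(id = peptides$id), parts)
  if ("label" %in% colnames(peptides)) out$label <- peptides$label
  out
}

#' Read and write feature-name manifests
#'
#' A manifest is a plain-text file with one feature name per line;
#' `#`-comments and blank lines are ignored. Manifests are how selected
#' subsets travel between the selection stage and [encode_selected()].
#'
#' @param path Manifest file path.
#' @return `read_manifest()`: character vector of feature names;
#'   `write_manifest()`: `path`, invisibly.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' @rdname read_manifest
#' @param names Character vector of feature names to write.
#' @export
write_manifest <- function(names, path) {
  writeLines(names, path)
  invisible(path)
}

#' The shipped seven-feature model manifest
#'
#' Path to (or contents of) the packaged manifest of the seven
#' slope-point features of the final reduced low-dimensional ACP model:
#' `GL.gap4`, `hydrophobicity_PRAM900101.Tr2332`,
#' `polarizability.2.residue0`, `Pc1.C`, `Xc1.K`, `Pc2.Hydrophobicity.8`,
#' `secondarystruct.1.residue0`.
#'
#' @param as_names Return the feature names (default) rather than the file
#'   path.
#' @return Character vector of seven feature names, or the manifest path.
#' @examples
#' model_7d_manifest()
#' @export
model_7d_manifest <- function(as_names = TRUE) {
  path <- system.file("extdata", "model_7d.manifest", package = "acpselect",
                      mustWork = TRUE)
  if (as_names) read_manifest(path) else path
}
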