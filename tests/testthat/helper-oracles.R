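# Brute-force enumeration oracles for every encoder: explicit loops over
# index tuples and residue letters, sharing no machinery with the package
# implementation. Used to freeze expected values and for the
# oracle-equivalence property test.

tabs <- property_tables()
ALPHA <- tabs$alphabet

random_peptide <- function(len) {
  paste(sample(ALPHA, len, replace = TRUE), collapse = "")
}

chars_of <- function(s) strsplit(s, "")[[1]]

oracle_aac <- function(s) {
  ch <- chars_of(s)
  out <- setNames(numeric(20), ALPHA)
  for (a in ALPHA) {
    n_a <- 0
    for (c in ch) if (c == a) n_a <- n_a + 1
    out[a] <- n_a / length(ch)
  }
  out
}

oracle_kmer <- function(s, k) {
  ch <- chars_of(s)
  n <- length(ch)
  counts <- new.env()
  for (i in 1:(n - k + 1)) {
    key <- paste(ch[i:(i + k - 1)], collapse = "")
    counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
  }
  nm <- character(0)
  for_names <- function(prefix, depth) {
    if (depth == 0) { nm <<- c(nm, prefix); return(invisible()) }
    for (a in ALPHA) for_names(paste0(prefix, a), depth - 1)
  }
  for_names("", k)
  out <- setNames(numeric(length(nm)), nm)
  for (key in ls(counts)) out[key] <- counts[[key]]
  out / (n - k + 1)
}

oracle_cksaap <- function(s, kmax) {
  ch <- chars_of(s)
  n <- length(ch)
  out <- numeric(0)
  for (k in 0:kmax) {
    block <- setNames(numeric(400),
                      unlist(lapply(ALPHA, function(a) paste0(a, ALPHA))))
    for (i in 1:(n - k - 1)) {
      key <- paste0(ch[i], ch[i + k + 1])
      block[key] <- block[key] + 1
    }
    names(block) <- paste0(names(block), ".gap", k)
    out <- c(out, block / (n - k - 1))
  }
  out
}

grp_of <- function(c) {
  for (g in names(tabs$gaac_groups)) {
    if (c %in% tabs$gaac_groups[[g]]) return(g)
  }
  stop("unmapped residue")
}

oracle_grouped_kmer <- function(s, k) {
  ch <- vapply(chars_of(s), grp_of, character(1))
  n <- length(ch)
  gn <- names(tabs$gaac_groups)
  nm <- character(0)
  for_names <- function(prefix, depth) {
    if (depth == 0) { nm <<- c(nm, prefix); return(invisible()) }
    for (g in gn) for_names(if (nzchar(prefix)) paste(prefix, g, sep = ".") else g,
                            depth - 1)
  }
  for_names("", k)
  out <- setNames(numeric(length(nm)), nm)
  for (i in 1:(n - k + 1)) {
    key <- paste(ch[i:(i + k - 1)], collapse = ".")
    out[key] <- out[key] + 1
  }
  out / (n - k + 1)
}

oracle_cksaagp <- function(s, kmax) {
  ch <- vapply(chars_of(s), grp_of, character(1))
  n <- length(ch)
  gn <- names(tabs$gaac_groups)
  pair_names <- unlist(lapply(gn, function(a) paste(a, gn, sep = ".")))
  out <- numeric(0)
  for (k in 0:kmax) {
    block <- setNames(numeric(25), pair_names)
    for (i in 1:(n - k - 1)) {
      key <- paste(ch[i], ch[i + k + 1], sep = ".")
      block[key] <- block[key] + 1
    }
    names(block) <- paste0(names(block), ".gap", k)
    out <- c(out, block / (n - k - 1))
  }
  out
}

ct_class_idx <- function(c) {
  for (k in seq_along(tabs$ct_classes)) {
    if (c %in% tabs$ct_classes[[k]]) return(k)
  }
  stop("unmapped residue")
}

oracle_ct <- function(s) {
  ch <- vapply(chars_of(s), ct_class_idx, integer(1))
  n <- length(ch)
  nm <- character(0)
  for (a in 1:7) for (b in 1:7) for (c in 1:7) {
    nm <- c(nm, paste0("CT.", a, b, c))
  }
  out <- setNames(numeric(343), nm)
  for (i in 1:(n - 2)) {
    key <- paste0("CT.", ch[i], ch[i + 1], ch[i + 2])
    out[key] <- out[key] + 1
  }
  out / (n - 2)
}

ctd_grp <- function(c, prop) {
  p <- tabs$ctd_properties[[prop]]
  if (c %in% p$g1) 1L else if (c %in% p$g2) 2L else 3L
}

oracle_ctdc <- function(s) {
  ch <- chars_of(s)
  out <- numeric(0)
  for (prop in names(tabs$ctd_properties)) {
    g <- vapply(ch, ctd_grp, integer(1), prop = prop)
    v <- setNames(numeric(3), paste0(prop, ".G", 1:3))
    for (k in 1:3) v[k] <- sum(g == k) / length(ch)
    out <- c(out, v)
  }
  out
}

oracle_ctdt <- function(s) {
  ch <- chars_of(s)
  n <- length(ch)
  out <- numeric(0)
  for (prop in names(tabs$ctd_properties)) {
    g <- vapply(ch, ctd_grp, integer(1), prop = prop)
    v <- setNames(numeric(3), paste0(prop, c(".Tr1221", ".Tr1331", ".Tr2332")))
    for (i in 1:(n - 1)) {
      pair <- sort(c(g[i], g[i + 1]))
      if (pair[1] == 1 && pair[2] == 2) v[1] <- v[1] + 1
      if (pair[1] == 1 && pair[2] == 3) v[2] <- v[2] + 1
      if (pair[1] == 2 && pair[2] == 3) v[3] <- v[3] + 1
    }
    out <- c(out, v / (n - 1))
  }
  out
}

oracle_ctdd <- function(s) {
  ch <- chars_of(s)
  n <- length(ch)
  pct <- c(0, 25, 50, 75, 100)
  out <- numeric(0)
  for (prop in names(tabs$ctd_properties)) {
    g <- vapply(ch, ctd_grp, integer(1), prop = prop)
    for (k in 1:3) {
      pos <- which(g == k)
      v <- setNames(numeric(5), paste0(prop, ".", k, ".residue", pct))
      if (length(pos) > 0) {
        for (j in 1:5) {
          idx <- if (pct[j] == 0) 1 else ceiling(pct[j] / 100 * length(pos))
          v[j] <- pos[idx] / n * 100
        }
      }
      out <- c(out, v)
    }
  }
  out
}

std_scale <- function(name) {
  x <- tabs$paac_scales[[name]][ALPHA]
  (x - mean(x)) / sqrt(sum((x - mean(x))^2) / 20)
}

oracle_paac <- function(s, lambda, w) {
  ch <- chars_of(s)
  n <- length(ch)
  scales <- lapply(c("Hydrophobicity", "Hydrophilicity", "SideChainMass"),
                   std_scale)
  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    acc <- 0
    for (i in 1:(n - j)) {
      corr <- 0
      for (sc in scales) corr <- corr + (sc[ch[i + j]] - sc[ch[i]])^2 / 3
      acc <- acc + corr
    }
    theta[j] <- acc / (n - j)
  }
  f <- setNames(numeric(20), ALPHA)
  for (c in ch) f[c] <- f[c] + 1
  f <- f / n
  denom <- 1 + w * sum(theta)
  out <- c(f / denom, if (lambda > 0) w * theta / denom)
  names(out) <- c(paste0("Xc1.", ALPHA),
                  if (lambda > 0) paste0("Xc2.lambda.", seq_len(lambda)))
  out
}

oracle_apaac <- function(s, lambda, w) {
  ch <- chars_of(s)
  n <- length(ch)
  sc_names <- c("Hydrophobicity", "Hydrophilicity")
  scales <- lapply(sc_names, std_scale)
  tau <- numeric(0)
  tau_names <- character(0)
  for (j in seq_len(lambda)) {
    for (u in 1:2) {
      acc <- 0
      for (i in 1:(n - j)) acc <- acc + scales[[u]][ch[i]] * scales[[u]][ch[i + j]]
      tau <- c(tau, acc / (n - j))
      tau_names <- c(tau_names, paste0("Pc2.", sc_names[u], ".", j))
    }
  }
  f <- setNames(numeric(20), ALPHA)
  for (c in ch) f[c] <- f[c] + 1
  f <- f / n
  denom <- 1 + w * sum(tau)
  out <- c(f / denom, if (lambda > 0) w * tau / denom)
  names(out) <- c(paste0("Pc1.", ALPHA), tau_names)
  out
}

# strip id/label and return the named numeric feature vector of row i
feature_row <- function(tbl, i = 1) {
  cols <- setdiff(names(tbl), c("id", "label"))
  unlist(tbl[i, cols])
}
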