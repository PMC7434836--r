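pep <- function(...) {
  s <- c(...)
  tibble::tibble(id = sprintf("p%d", seq_along(s)), sequence = s)
}

test_that("encoder dimensions follow the documented contract", {
  p <- pep("GLWSKIKEVGKEAAKAAAKAAGKAALGAVSDTV")  # length 33 covers all minima
  dims <- c(
    encode_aac = 20, encode_dpc = 400, encode_tpc = 8000,
    encode_gaac = 5, encode_gdpc = 25, encode_gtpc = 125,
    encode_ct = 343, encode_ctdc = 39, encode_ctdt = 39, encode_ctdd = 195
  )
  for (fn in names(dims)) {
    out <- get(fn)(p)
    expect_identical(ncol(out) - 1L, as.integer(dims[[fn]]), label = fn)
  }
  expect_identical(ncol(encode_cksaap(p, kmax = 5)) - 1L, 2400L)
  expect_identical(ncol(encode_cksaagp(p, kmax = 3)) - 1L, 100L)
  expect_identical(ncol(encode_paac(p, lambda = 8)) - 1L, 28L)
  expect_identical(ncol(encode_apaac(p, lambda = 8)) - 1L, 36L)
  # column order is deterministic
  expect_identical(names(encode_cksaap(p, 2)), names(encode_cksaap(pep("AAAAA"), 2)))
})

test_that("worked example CRACRKDSMVN: AAC letter counts and k=0 pair counts", {
  p <- pep("CRACRKDSMVN")
  a <- encode_aac(p)
  expect_equal(a$C, 2 / 11)
  expect_equal(a$R, 2 / 11)
  expect_equal(a$A, 1 / 11)
  ck <- encode_cksaap(p, kmax = 0)
  expect_equal(ck[["CR.gap0"]], 2 / 10)
  expect_equal(ck[["AC.gap0"]], 1 / 10)
  expect_equal(ck[["AA.gap0"]], 0)
  expect_equal(ck[["CQ.gap0"]], 0)
})

test_that("forced k-mer cases: homopolymers and planted pairs", {
  expect_equal(encode_aac(pep("AAAA"))$A, 1)
  expect_equal(sum(feature_row(encode_aac(pep("AAAA"))) != 0), 1)
  expect_equal(encode_dpc(pep("AAAA"))$AA, 1)
  expect_equal(encode_cksaap(pep("AAAA"), 1)[["AA.gap1"]], 1)  # pairs (1,3),(2,4)
  expect_equal(encode_gaac(pep("GGGG"))$aliphatic, 1)
  expect_equal(sum(feature_row(encode_gaac(pep("GGGG"))) != 0), 1)
  # K and R are both positively charged: the only dipeptide group pair
  expect_equal(encode_gdpc(pep("KRKR"))[["positivecharge.positivecharge"]], 1)
})

test_that("length preconditions raise errors naming the scheme and peptide", {
  expect_error(encode_dpc(pep("A")), "DPC")
  expect_error(encode_tpc(pep("AC")), "TPC")
  expect_error(encode_cksaap(pep("ACDE"), kmax = 3), "CKSAAP")
  expect_error(encode_paac(pep("ACDEF"), lambda = 5), "PAAC.*p1")
  expect_error(encode_ct(pep("AC")), "CT")
})

test_that("conjoint triads treat class-equivalent residues equally", {
  # G,L,M map to classes 1,2,3 — same as V,F,T
  glm <- encode_ct(pep("GLM"))
  vft <- encode_ct(pep("VFT"))
  expect_equal(feature_row(glm), feature_row(vft))
  expect_equal(glm[["CT.123"]], 1)

  ggg <- feature_row(encode_ct(pep("GGG")))
  expect_equal(sum(ggg != 0), 1)

  # G, A, V share class 1: all 4 overlapping triads identical
  gav <- encode_ct(pep("GAVGAV"))
  expect_equal(gav[["CT.111"]], 1)
  expect_equal(sum(feature_row(gav) != 0), 1)

  # min-max variant: zero-count triads map to 0, the max to 1
  mm <- feature_row(encode_ct(pep("GAVGAV"), normalize = "minmax"))
  expect_equal(max(mm), 1)
  expect_equal(sum(mm == 0), 342)
})

test_that("C/T/D descriptors behave on homopolymers and partitions", {
  h <- pep("AAAAA")
  expect_true(all(feature_row(encode_ctdt(h)) == 0))  # no group changes

  dd <- encode_ctdd(h)
  # for the group containing A under every property: first occurrence at 1,
  # last at 5
  for (prop in names(property_tables()$ctd_properties)) {
    g <- ctd_grp("A", prop)
    expect_equal(dd[[paste0(prop, ".", g, ".residue0")]], 20)
    expect_equal(dd[[paste0(prop, ".", g, ".residue100")]], 100)
  }

  # composition features of one property sum to 1 over its 3 groups
  p <- pep("GLWSKIKEVGKEAAKAAAKA")
  cc <- encode_ctdc(p)
  for (prop in c("charge", "polarity", "hydrophobicity_PRAM900101")) {
    expect_equal(sum(unlist(cc[paste0(prop, ".G", 1:3)])), 1)
  }

  # absent group: all five distribution descriptors are 0
  kr <- encode_ctdd(pep("KRKRKR"))
  expect_true(all(unlist(kr[paste0("charge.3.residue", c(0, 25, 50, 75, 100))]) == 0))
})

test_that("PAAC/APAAC reduce to AAC in the lambda -> 0 and w -> 0 limits", {
  p <- pep("GLWSKIKEVGKEAAKAAAKA", "CRACRKDSMVN")
  aac <- feature_row(encode_aac(p), 1)
  expect_equal(unname(feature_row(encode_paac(p, lambda = 0), 1)), unname(aac))
  expect_equal(unname(feature_row(encode_paac(p, lambda = 5, w = 0), 1)[1:20]),
               unname(aac))
  expect_equal(unname(feature_row(encode_apaac(p, lambda = 5, w = 0), 1)[1:20]),
               unname(aac))
  # identical residues: zero squared scale differences, so theta = 0
  h <- encode_paac(pep("AAAAAAAAAA"), lambda = 1)
  expect_equal(h[["Xc1.A"]], 1)
  expect_equal(h[["Xc2.lambda.1"]], 0)
})

test_that("composition-family vectors sum to 1 (gap blocks separately)", {
  withr::with_seed(42, {
    seqs <- vapply(sample(8:30, 12, replace = TRUE), random_peptide,
                   character(1))
  })
  p <- pep(seqs)
  for (enc in list(encode_aac, encode_dpc, encode_tpc, encode_gaac,
                   encode_gdpc, encode_gtpc)) {
    sums <- rowSums(as.matrix(dplyr::select(enc(p), -id)))
    expect_equal(sums, rep(1, nrow(p)), tolerance = 1e-12)
  }
  ck <- encode_cksaap(p, kmax = 3)
  gp <- encode_cksaagp(p, kmax = 3)
  for (k in 0:3) {
    ksum <- rowSums(as.matrix(ck[, grepl(paste0("\\.gap", k, "$"), names(ck))]))
    expect_equal(ksum, rep(1, nrow(p)), tolerance = 1e-12)
    gsum <- rowSums(as.matrix(gp[, grepl(paste0("\\.gap", k, "$"), names(gp))]))
    expect_equal(gsum, rep(1, nrow(p)), tolerance = 1e-12)
  }
})

test_that("encoders are permutation-covariant: shuffling rows shuffles rows only", {
  withr::with_seed(9, {
    seqs <- vapply(rep(12, 6), random_peptide, character(1))
  })
  p <- pep(seqs)
  perm <- c(4, 1, 6, 3, 2, 5)
  for (enc in list(encode_aac, encode_ctdd,
                   function(x) encode_paac(x, lambda = 4))) {
    straight <- enc(p)
    shuffled <- enc(p[perm, ])
    expect_equal(as.data.frame(shuffled), as.data.frame(straight[perm, ]),
                 ignore_attr = TRUE)
  }
})

test_that("label columns pass through encoders untouched", {
  d <- simulate_peptides(n_pos = 3, n_neg = 4, bias = 1, seed = 2)
  out <- encode_aac(d)
  expect_named(out, c("id", property_tables()$alphabet, "label"))
  expect_equal(out$label, d$label)
})
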