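test_that("global alignment handles identity, single gaps and hand DP", {
  a <- global_align("PFCNAFTGC", "PFCNAFTGC")
  expect_equal(a$length, 9L)
  expect_false(grepl("-", paste(a$members, collapse = "")))
  b <- global_align("MK", "MAK")
  expect_equal(b$length, 3L)
  expect_equal(sum(strsplit(paste(b$members, collapse = ""),
                            "")[[1L]] == "-"), 1L)
})

test_that("percent identity honours both denominator conventions", {
  expect_equal(percent_identity(global_align("AAAA", "AAAT")), 75)
  aln <- alignment_set(c(x = "AA--", y = "AAGG"))
  expect_equal(percent_identity(aln, "all_columns"), 50)
  expect_equal(percent_identity(aln, "ungapped_columns"), 100)
  set.seed(31)
  for (i in 1:10) {
    s <- paste(sample(c("A", "R", "N", "D", "W"), 12L, TRUE), collapse = "")
    expect_equal(percent_identity(global_align(s, s)), 100)
  }
  expect_error(percent_identity(alignment_set(c(a = "A-", b = "-A")),
                                "ungapped_columns"), "zero comparable")
})

test_that("progressive alignment is deterministic and order-invariant", {
  aln <- progressive_align(c(a = "MKA", b = "MA", c = "MKA"))
  expect_equal(aln$length, 3L)
  expect_equal(unname(aln$members[["b"]] == "M-A" |
                        aln$members[["b"]] == "MA-"), TRUE)
  same <- progressive_align(c(a = "MMMM", b = "MMMM", c = "MMMM"))
  expect_false(grepl("-", paste(same$members, collapse = "")))
  seqs <- c(s1 = "MKACD", s2 = "MACD", s3 = "MKACD", s4 = "MKAWD")
  a1 <- progressive_align(seqs)
  a2 <- progressive_align(seqs[c(3L, 1L, 4L, 2L)])
  expect_equal(a1$members[sort(names(seqs))], a2$members[sort(names(seqs))])
})

test_that("conservation shading follows the dark/grey figure convention", {
  expect_equal(conservation_shading(alignment_set(
    setNames(rep("F", 5L), paste0("s", 1:5)))), "identical")
  expect_equal(conservation_shading(alignment_set(
    setNames(c("F", "F", "F", "F", "Y"), paste0("s", 1:5)))), "high")
  expect_equal(conservation_shading(alignment_set(
    setNames(c("F", "F", "F", "Y", "Y"), paste0("s", 1:5)))), "low")
  # category depends only on the column multiset
  aln1 <- alignment_set(c(a = "FY", b = "FY", c = "YY"))
  aln2 <- alignment_set(c(a = "FY", b = "YY", c = "FY"))
  expect_equal(conservation_shading(aln1), conservation_shading(aln2))
})

test_that("logo information content follows the corrected entropy formula", {
  pure <- alignment_set(setNames(rep("F", 4L), paste0("s", 1:4)))
  expect_equal(sequence_logo(pure, FALSE)$information, log2(20))
  aas20 <- c("A","R","N","D","C","Q","E","G","H","I",
             "L","K","M","F","P","S","T","W","Y","V")
  unif <- alignment_set(setNames(aas20, paste0("s", 1:20)))
  expect_equal(sequence_logo(unif, FALSE)$information, 0)
  # 50/50 two residues, n = 10, correction on: closed form
  half <- alignment_set(setNames(c(rep("F", 5L), rep("Y", 5L)),
                                 paste0("s", 1:10)))
  expect_equal(sequence_logo(half, TRUE)$information,
               max(0, log2(20) - (1 + 19 / (2 * log(2) * 10))))
  # information weakly decreases as the modal frequency drops at fixed n
  f9 <- alignment_set(setNames(c(rep("F", 9L), "Y"), paste0("s", 1:10)))
  f6 <- alignment_set(setNames(c(rep("F", 6L), rep("Y", 4L)),
                               paste0("s", 1:10)))
  expect_gte(sequence_logo(f9)$information, sequence_logo(f6)$information)
})

test_that("pairwise aligners agree with exhaustive enumeration and an independent aligner", {
  B62 <- substitution_matrix("BLOSUM62")
  # exhaustive oracle on all pairs of short strings over a 3-letter alphabet
  strs <- all_strings(c("A", "C", "D"), 3L)
  for (x in strs) for (y in strs) {
    expect_equal(attr(global_align(x, y, B62, 2, 0.5), "score"),
                 enum_global_score(x, y, B62, 2, 0.5), info = paste(x, y))
  }
  set.seed(41)
  idx <- expand.grid(seq_along(strs), seq_along(strs))
  pick <- idx[sample(nrow(idx), 150L), ]
  for (k in seq_len(nrow(pick))) {
    x <- strs[pick[k, 1L]]; y <- strs[pick[k, 2L]]
    expect_equal(local_align(x, y, B62, 2, 0.5)$score,
                 enum_local_score(x, y, B62, 2, 0.5), info = paste(x, y))
  }
  # independent aligner cross-check on longer random pairs
  aas <- rownames(B62)[1:20]
  for (k in 1:60) {
    x <- paste(sample(aas, sample(2:6, 1L), TRUE), collapse = "")
    y <- paste(sample(aas, sample(2:6, 1L), TRUE), collapse = "")
    ref_g <- Biostrings::pairwiseAlignment(x, y, substitutionMatrix = B62,
                                           gapOpening = 10, gapExtension = 0.5,
                                           type = "global", scoreOnly = TRUE)
    expect_equal(attr(global_align(x, y, B62, 10, 0.5), "score"), ref_g,
                 info = paste("NW", x, y))
    ref_l <- Biostrings::pairwiseAlignment(x, y, substitutionMatrix = B62,
                                           gapOpening = 10, gapExtension = 0.5,
                                           type = "local", scoreOnly = TRUE)
    expect_equal(local_align(x, y, B62, 10, 0.5)$score, max(ref_l, 0),
                 info = paste("SW", x, y))
  }
})
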