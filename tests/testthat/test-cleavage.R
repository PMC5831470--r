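test_that("rule tiers behave on hand-worked cases", {
  # unconditional KR
  s1 <- find_cleavage_sites("AAAGKRSSS")
  expect_length(s1, 1L)
  expect_equal(s1[[1L]]$motif_class, "KR")
  expect_equal(s1[[1L]]$cut_after, 5L)
  expect_equal(s1[[1L]]$confidence, "high")
  # lone mono-R without upstream basic: silent
  expect_length(find_cleavage_sites("AAARSSS"), 0L)
  # mono-R fires with a basic at -3 (hand-enumerated)
  s2 <- find_cleavage_sites("AARXXRSSS")
  expect_length(s2, 1L)
  expect_equal(s2[[1L]]$cut_after, 5L)
  expect_equal(s2[[1L]]$motif_class, "monoR")
  # proline and cysteine exclusions suppress RR but never KR
  expect_length(find_cleavage_sites("AAARRPSS"), 0L)
  expect_length(find_cleavage_sites("AACARRSS"), 0L)
  expect_length(find_cleavage_sites("AACAKRSS"), 1L)
  # overlapping run resolves to the rightmost admissible site
  s3 <- find_cleavage_sites("AAAKRRSSS")
  expect_length(s3, 1L)
  expect_equal(s3[[1L]]$cut_after, 5L)
  expect_length(find_cleavage_sites(""), 0L)
})

test_that("excision processes amide donors, pyroglutamate and spacers", {
  sites <- find_cleavage_sites("QLNFSTGWGKRDDE")
  pep <- excise_peptides("QLNFSTGWGKRDDE", NULL, sites)
  expect_equal(pep$sequence, "QLNFSTGW")
  expect_true(pep$amidated[1L] && pep$pyroglutamate[1L])
  expect_equal(format_peptide_notation(pep$sequence[1L], pep$amidated[1L],
                                       pep$pyroglutamate[1L]), "pQLNFSTGWa")
  pep2 <- excise_peptides("SDVIIRYGKRDDE", NULL,
                          find_cleavage_sites("SDVIIRYGKRDDE"))
  expect_equal(format_peptide_notation(pep2$sequence[1L], pep2$amidated[1L],
                                       pep2$pyroglutamate[1L]), "SDVIIRYa")
  # a 3-mer fragment is a spacer, not a peptide
  pep3 <- excise_peptides("ADEKRQLNFSTGWGKR", NULL,
                          find_cleavage_sites("ADEKRQLNFSTGWGKR"))
  expect_equal(pep3$sequence, "QLNFSTGW")
  expect_equal(attr(pep3, "spacers")$sequence[1L], "ADE")
  # site outside the propeptide is an integrity error
  expect_error(excise_peptides("QLNF", NULL,
                               list(list(cut_after = 10L))), "outside")
})

test_that("cysteine census counts from the C-terminus", {
  cc <- cysteine_census("GQAKGRVYWRCYFNAVTCF")
  expect_equal(cc$cys_positions_from_C, c(-9L, -2L))
  expect_equal(cc$n_disulfides, 1L)
  cc2 <- cysteine_census("PFCNAFTGC")
  expect_equal(cc2$cys_positions_from_C, c(-7L, -1L))
  expect_equal(cc2$n_disulfides, 1L)
  cc3 <- cysteine_census("AAAA")
  expect_length(cc3$cys_positions_from_C, 0L)
  expect_equal(cc3$n_disulfides, 0L)
  odd <- cysteine_census("CACAC")
  expect_true(odd$odd_cys)
  expect_equal(odd$n_disulfides, 1L)
})

test_that("residues are conserved: signal + fragments reassemble the precursor", {
  set.seed(77)
  tpls <- default_family_templates()
  for (i in 1:25) {
    g <- generate_precursor(tpls[[sample(length(tpls), 1L)]])
    s <- g$record$residues
    sig <- list(cleavage_index = g$signal_length, score = 1, source = "external")
    sites <- find_cleavage_sites(substring(s, g$signal_length + 1L))
    pep <- excise_peptides(s, sig, sites)
    # every amidated peptide has G at its excision boundary in the precursor
    for (r in seq_len(nrow(pep)))
      if (pep$amidated[r])
        expect_equal(substring(s, pep$end[r] + 1L, pep$end[r] + 1L), "G")
    # fragment spans (peptides + spacers) tile the propeptide
    spans <- rbind(pep[, c("start", "end")],
                   attr(pep, "spacers")[, c("start", "end")])
    spans <- spans[order(spans$start), ]
    expect_true(all(spans$start >= g$signal_length))
    expect_true(all(spans$end <= nchar(s)))
    expect_true(all(diff(spans$start) > 0))
  }
})

test_that("cleavage engine matches the brute-force rule evaluator", {
  # exhaustive over short strings on the adversarial alphabet
  alpha <- c("A", "K", "R", "P", "C")
  for (s in all_strings(alpha, 5L)) {
    got <- find_cleavage_sites(s)
    want <- bf_cleavage_sites(s)
    expect_equal(lapply(got, `[`, c("cut_after", "motif_class")), want,
                 info = s)
  }
  # seeded random longer strings
  set.seed(515)
  for (i in 1:1500) {
    s <- paste(sample(alpha, sample(6:12, 1L), TRUE), collapse = "")
    got <- find_cleavage_sites(s)
    want <- bf_cleavage_sites(s)
    expect_equal(lapply(got, `[`, c("cut_after", "motif_class")), want,
                 info = s)
  }
})
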