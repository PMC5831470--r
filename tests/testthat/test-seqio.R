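test_that("read_fasta joins wrapped lines, keeps file order, validates residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a desc here", "PFCN", "AFTGC", ">b", "MK", ">c", "QQ"), f)
  recs <- read_fasta(f, "protein")
  expect_length(recs, 3L)
  expect_equal(names(recs), c("a", "b", "c"))
  expect_equal(recs$a$residues, "PFCNAFTGC")
  expect_equal(recs$a$desc, "desc here")

  writeLines(c(">a", "", ">b", "MK"), f)
  expect_error(read_fasta(f, "protein"), "empty sequence")

  writeLines(c(">a", "MKZ"), f)
  expect_error(read_fasta(f, "protein"), "position 3")

  writeLines(character(0), f)
  expect_error(read_fasta(f, "protein"), "no records")
})

test_that("FASTA round trip preserves records and wraps at 60 columns", {
  set.seed(11)
  recs <- lapply(1:5, function(i) {
    seq_record(paste0("r", i),
               paste(sample(c("A", "C", "D", "M", "K"), 150, TRUE),
                     collapse = ""),
               "protein", desc = "round trip")
  })
  names(recs) <- vapply(recs, `[[`, "", "id")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  expect_true(all(nchar(readLines(f)) <= 61L))
  back <- read_fasta(f, "protein")
  expect_equal(lapply(back, `[[`, "residues"), lapply(recs, `[[`, "residues"))
  expect_equal(lapply(back, `[[`, "desc"), lapply(recs, `[[`, "desc"))
})

test_that("six-frame translation renders frames, stops and the length law", {
  r <- seq_record("x", "ATGAAA", "nucleotide")
  fr <- six_frame_translate(r)
  expect_equal(fr[["x_frame+1"]]$residues, "MK")
  expect_equal(six_frame_translate(seq_record("y", "TTTCAT",
                                              "nucleotide"))[["y_frame-1"]]$residues,
               "MK")
  expect_equal(six_frame_translate(seq_record("z", "ATGTAA",
                                              "nucleotide"))[["z_frame+1"]]$residues,
               "M*")
  # len(frame k) == floor((L - |k| + 1) / 3)
  set.seed(4)
  for (L in c(3L, 7L, 20L, 31L)) {
    s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    fr <- six_frame_translate(seq_record("w", s, "nucleotide"))
    lens <- vapply(fr, function(x) nchar(x$residues), 0L)
    expect_equal(unname(lens),
                 rep(vapply(1:3, function(k) (L - k + 1L) %/% 3L, 0L), 2L))
  }
  expect_warning(six_frame_translate(seq_record("s", "AT", "nucleotide")),
                 "shorter")
})

test_that("peptide notation parses and regenerates Table-1 conventions", {
  p <- parse_peptide_notation("pQLNFSTGWa")
  expect_equal(p$sequence, "QLNFSTGW")
  expect_true(p$amidated && p$pyroglutamate && !p$partial)
  expect_equal(format_peptide_notation(p$sequence, p$amidated,
                                       p$pyroglutamate), "pQLNFSTGWa")
  q <- parse_peptide_notation("...MGASFIRFa")
  expect_true(q$partial && q$amidated && !q$pyroglutamate)
  tab <- published_peptides()
  regen <- vapply(seq_len(nrow(tab)), function(i)
    format_peptide_notation(tab$sequence[i], tab$amidated[i],
                            tab$pyroglutamate[i]), "")
  expect_equal(regen, sub("^\\.\\.\\.", "", tab$notation))
})

test_that("annotation report emits Table-1 notation and flags empty precursors", {
  rec <- seq_record("p1", "MKLLVLLLALFAASADEEGSEEKRQLNFSTGWGKREEDDSE",
                    "protein")
  ann <- annotate_precursor(rec, species = "sp", superfamily = "sf")
  out <- write_annotation_report(list(ann), withr::local_tempfile())
  tab <- read.delim(out[["table"]])
  expect_equal(tab$peptide_seq[1L], "pQLNFSTGWa")
  expect_equal(tab$species[1L], "sp")
  # zero-peptide precursor gets a no-peptides row
  empty <- annotate_precursor(seq_record("p2", strrep("MDE", 12L), "protein"))
  out2 <- write_annotation_report(list(empty), withr::local_tempfile())
  tab2 <- read.delim(out2[["table"]])
  expect_equal(tab2$flag[1L], "no-peptides")
  # overlapping spans are an integrity error
  bad <- ann
  bad$peptides <- rbind(ann$peptides, ann$peptides)
  bad$peptides$start[2L] <- bad$peptides$start[1L] + 1L
  expect_error(write_annotation_report(list(bad), withr::local_tempfile()),
               "overlapping")
})
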