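#' @useDynLib npmine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table head tail
NULL

PROTEIN_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                      "F","P","S","T","W","Y","V","X","*")
NUCLEOTIDE_ALPHABET <- c("A","C","G","T","U","N")

#' Create a sequence record
#'
#' A light container for a single protein or nucleotide sequence with its
#' identifier and free-text description. Residues are uppercased and
#' validated against the declared alphabet (the 20 amino acids plus `X`
#' and `*` for proteins; `ACGTUN` for nucleotides).
#'
#' @param id identifier (string, no whitespace).
#' @param residues sequence string.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param desc free-text description (may be empty).
#' @return An object of class `seq_record` with fields `id`, `desc`,
#'   `residues` and `alphabet`.
#' @export
seq_record <- function(id, residues, alphabet = c("protein", "nucleotide"),
                       desc = "") {
  alphabet <- match.arg(alphabet)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("record identifier must be a non-empty string")
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues))
    stop(sprintf("record '%s' has an empty sequence", id))
  allowed <- if (alphabet == "protein") PROTEIN_ALPHABET else NUCLEOTIDE_ALPHABET
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% allowed)
  if (length(bad))
    stop(sprintf("record '%s': residue '%s' at position %d not in %s alphabet",
                 id, chars[bad[1L]], bad[1L], alphabet))
  structure(list(id = id, desc = desc, residues = residues,
                 alphabet = alphabet),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s [%s, %d aa/nt]>\n", x$id, x$alphabet,
              nchar(x$residues)))
  invisible(x)
}

#' Read a FASTA file into a list of sequence records
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; wrapping and
#' trailing whitespace are normalised, residues uppercased, and every
#' record validated against `alphabet`.
#'
#' @param path FASTA file path.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return Named list of [seq_record] objects in file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf("failed to parse FASTA '%s': %s",
                                                   path, conditionMessage(e))))
  if (length(set) == 0L) stop(sprintf("no records in FASTA file '%s'", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  recs <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- as.character(set[[i]])
    if (!nzchar(gsub("[[:space:]]", "", s)))
      stop(sprintf("record '%s' has an empty sequence", ids[i]))
    recs[[i]] <- seq_record(ids[i], s, alphabet, descs[i])
  }
  names(recs) <- ids
  recs
}

#' Write sequence records to FASTA
#'
#' @param records list of [seq_record] (or a single record).
#' @param path output path.
#' @param width column wrap (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$desc)) paste(r$id, r$desc) else r$id
    writeLines(paste0(">", header), con)
    s <- r$residues
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

REVCOMP_MAP <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")

#' Six-frame translation of a nucleotide record
#'
#' Translates the three forward frames and the three frames of the reverse
#' complement with the standard (or any NCBI-numbered) genetic code via
#' [Biostrings::getGeneticCode()]. Stop codons are rendered as `*`,
#' ambiguous codons as `X`. The frame tag (`_frame+1` ... `_frame-3`) is
#' appended to the record identifier.
#'
#' @param record nucleotide [seq_record].
#' @param code NCBI translation table id (default `"1"`, the standard code).
#' @return List of six protein [seq_record]s (frames +1, +2, +3, -1, -2, -3).
#'   Frames shorter than one codon yield records with residues `""` replaced
#'   by an empty-protein placeholder and a warning.
#' @export
six_frame_translate <- function(record, code = "1") {
  stopifnot(inherits(record, "seq_record"))
  if (record$alphabet != "nucleotide")
    stop("six_frame_translate requires a nucleotide record")
  s <- chartr("U", "T", record$residues)
  if (nchar(s) < 3L)
    warning(sprintf("record '%s' shorter than one codon; all frames empty",
                    record$id))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  rc <- paste(rev(unname(REVCOMP_MAP[chars])), collapse = "")
  gc_tab <- Biostrings::getGeneticCode(code)
  translate_frame <- function(seqstr, offset) {
    sub <- substring(seqstr, offset + 1L, nchar(seqstr))
    n_codon <- nchar(sub) %/% 3L
    if (n_codon == 0L) return("")
    dna <- Biostrings::DNAString(substring(sub, 1L, n_codon * 3L))
    as.character(Biostrings::translate(dna, genetic.code = gc_tab,
                                       if.fuzzy.codon = "X"))
  }
  frames <- list()
  labels <- c("+1", "+2", "+3", "-1", "-2", "-3")
  seqs <- c(lapply(0:2, function(o) translate_frame(s, o)),
            lapply(0:2, function(o) translate_frame(rc, o)))
  for (i in seq_along(seqs)) {
    id <- paste0(record$id, "_frame", labels[i])
    frames[[id]] <- if (nzchar(seqs[[i]]))
      seq_record(id, seqs[[i]], "protein", record$desc)
    else
      structure(list(id = id, desc = record$desc, residues = "",
                     alphabet = "protein"), class = "seq_record")
  }
  frames
}

#' Parse Table-1 style peptide notation
#'
#' In the field's shorthand a trailing `a` denotes C-terminal amidation, a
#' leading `pQ` an N-terminal pyroglutamate (the residue itself stays `Q`),
#' and a leading ellipsis (`...` or the Unicode character) marks a partial
#' peptide.
#'
#' @param notation peptide string in shorthand notation.
#' @return List with `sequence` (plain uppercase residues), `amidated`,
#'   `pyroglutamate`, `partial`.
#' @export
parse_peptide_notation <- function(notation) {
  x <- trimws(notation)
  partial <- grepl("^(\\.\\.\\.|…)", x)
  x <- sub("^(\\.\\.\\.|…)", "", x)
  pq <- startsWith(x, "pQ")
  if (pq) x <- sub("^p", "", x)
  amid <- grepl("a$", x)
  if (amid) x <- sub("a$", "", x)
  list(sequence = toupper(x), amidated = amid, pyroglutamate = pq,
       partial = partial)
}

#' Format a peptide in Table-1 style notation
#'
#' Inverse of [parse_peptide_notation()].
#'
#' @param sequence plain residue string (first residue `Q` if pyroglutamate).
#' @param amidated logical.
#' @param pyroglutamate logical.
#' @param partial logical; partial peptides carry no ellipsis, only the flag
#'   column in reports.
#' @return Notation string.
#' @export
format_peptide_notation <- function(sequence, amidated = FALSE,
                                    pyroglutamate = FALSE, partial = FALSE) {
  out <- sequence
  if (pyroglutamate) {
    if (!startsWith(out, "Q"))
      stop("pyroglutamate peptide must begin with Q")
    out <- paste0("p", out)
  }
  if (amidated) out <- paste0(out, "a")
  out
}

#' Write the annotated-precursor report
#'
#' Produces (i) a plain-text report with one block per precursor listing the
#' signal region, cleavage signals, mature peptides, amidation donors,
#' pyroglutamate positions and cysteines with 1-based inclusive coordinate
#' spans, and (ii) a TSV with one row per mature peptide using the shorthand
#' notation (`a` suffix = amide, `pQ` prefix = pyroglutamate).
#'
#' @param annotated list of annotated precursors as returned by
#'   [annotate_precursor()].
#' @param path basename for outputs; writes `<path>.txt` and `<path>.tsv`.
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_annotation_report <- function(annotated, path) {
  txt <- character(0)
  rows <- list()
  for (ann in annotated) {
    rec <- ann$record
    pep <- ann$peptides
    if (nrow(pep) > 1L) {
      o <- order(pep$start)
      p2 <- pep[o, ]
      if (any(p2$start[-1L] < p2$end[-nrow(p2)]))
        stop(sprintf("precursor '%s': overlapping peptide spans", rec$id))
    }
    txt <- c(txt, sprintf("## %s (%s) family=%s", rec$id,
                          if (nzchar(rec$desc)) rec$desc else "-",
                          if (is.na(ann$family)) "unassigned" else ann$family),
             rec$residues)
    if (!is.null(ann$signal)) {
      txt <- c(txt, sprintf("  signal   [1..%d] score=%.3f (%s)",
                            ann$signal$cleavage_index, ann$signal$score,
                            ann$signal$source))
    } else {
      txt <- c(txt, "  signal   absent")
    }
    if (length(ann$sites)) {
      for (s in ann$sites)
        txt <- c(txt, sprintf("  cleavage <%d> %s (%s)", s$cut_after + 1L,
                              s$motif_class, s$confidence))
    }
    if (nrow(pep) == 0L) {
      txt <- c(txt, "  peptides none [no-peptides]")
      rows[[length(rows) + 1L]] <- data.frame(
        species = ann$species, superfamily = ann$superfamily,
        precursor_id = rec$id,
        family = if (is.na(ann$family)) "unassigned" else ann$family,
        peptide_seq = "", start = NA_integer_, end = NA_integer_,
        amidated = NA, pyroglutamate = NA, n_cys = NA_integer_,
        partial = NA, flag = "no-peptides",
        stringsAsFactors = FALSE)
    } else {
      for (i in seq_len(nrow(pep))) {
        p <- pep[i, ]
        nota <- format_peptide_notation(p$sequence, p$amidated,
                                        p$pyroglutamate, p$partial)
        feats <- c(
          if (p$amidated) sprintf("amide-donor G@%d", p$end + 1L),
          if (p$pyroglutamate) sprintf("pQ@%d", p$start + 1L),
          if (p$n_cys > 0) sprintf("Cys x%d", p$n_cys),
          if (p$partial) "partial")
        txt <- c(txt, sprintf("  peptide  (%d..%d) %s%s", p$start + 1L, p$end,
                              nota,
                              if (length(feats)) paste0(" [", paste(feats, collapse = "; "), "]") else ""))
        rows[[length(rows) + 1L]] <- data.frame(
          species = ann$species, superfamily = ann$superfamily,
          precursor_id = rec$id,
          family = if (is.na(ann$family)) "unassigned" else ann$family,
          peptide_seq = nota, start = p$start + 1L, end = p$end,
          amidated = p$amidated, pyroglutamate = p$pyroglutamate,
          n_cys = p$n_cys, partial = p$partial, flag = "",
          stringsAsFactors = FALSE)
      }
    }
    txt <- c(txt, "")
  }
  txt_path <- paste0(path, ".txt")
  tsv_path <- paste0(path, ".tsv")
  writeLines(txt, txt_path, useBytes = TRUE)
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(species = character(0), superfamily = character(0),
                      precursor_id = character(0), family = character(0),
                      peptide_seq = character(0), start = integer(0),
                      end = integer(0), amidated = logical(0),
                      pyroglutamate = logical(0), n_cys = integer(0),
                      partial = logical(0), flag = character(0))
  write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(report = txt_path, table = tsv_path))
}
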