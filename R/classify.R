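#' Fetch a bundled substitution matrix
#'
#' @param name `"BLOSUM62"` (Smith-Waterman default) or `"PAM250"`
#'   (alternative for ClustalX-parameter global alignment).
#' @return Numeric substitution matrix with residue row/column names.
#' @export
substitution_matrix <- function(name = c("BLOSUM62", "PAM250")) {
  name <- match.arg(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  as.matrix(e[[name]])
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated matrix layout used by BLAST
#' (`#` comments, one header row of residues, one labelled row per residue).
#'
#' @param path matrix file.
#' @return Numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  mat <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(cols))))
  rownames(mat) <- vapply(rows, `[[`, "", 1L)
  colnames(mat) <- cols
  mat
}

.encode_seq <- function(s, mat) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  idx <- match(chars, rownames(mat))
  xi <- match("X", rownames(mat))
  if (any(is.na(idx))) {
    if (is.na(xi)) stop("residue not in substitution matrix and no X column")
    idx[is.na(idx)] <- xi
  }
  idx
}

.decode_aln <- function(codes, mat) {
  out <- character(length(codes))
  out[codes == 0L] <- "-"
  out[codes != 0L] <- rownames(mat)[codes[codes != 0L]]
  paste(out, collapse = "")
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' A gap of length L costs `gap_open + gap_extend * L`. Traceback is
#' deterministic with preference diagonal > up > left. Residues absent from
#' the matrix are scored through its `X` column.
#'
#' @param query,target protein strings.
#' @param matrix substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend affine gap parameters.
#' @return List with `score`, `query_aln`, `target_aln` (gapped strings) and
#'   the 1-based aligned span in each sequence. An empty best alignment
#'   (e.g. against `""`) has score 0.
#' @export
local_align <- function(query, target, matrix = substitution_matrix("BLOSUM62"),
                        gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(query) || !nzchar(target))
    return(list(score = 0, query_aln = "", target_aln = "",
                query_start = 0L, query_end = 0L,
                target_start = 0L, target_end = 0L))
  res <- .cpp_pair_align(.encode_seq(query, matrix),
                         .encode_seq(target, matrix),
                         matrix, gap_open, gap_extend, TRUE)
  list(score = res$score,
       query_aln = .decode_aln(res$a_aln, matrix),
       target_aln = .decode_aln(res$b_aln, matrix),
       query_start = res$a_start, query_end = res$a_end,
       target_start = res$b_start, target_end = res$b_end)
}

#' Load the neuropeptide family motif registry
#'
#' The bundled registry transcribes the C-terminal (and where needed
#' N-terminal) consensus motifs of ~30 insect neuropeptide families
#' (FXPRLamide pyrokinins, RLRFamide sNPF, FGLamide allatostatin A, ...)
#' together with their amidation and pyroglutamate expectations.
#'
#' @param path YAML registry; default the bundled
#'   `extdata/family_motifs.yaml`.
#' @return List of `family_motif` entries: `family`, `c_pattern`,
#'   `n_pattern`, `requires_amide`, `requires_pq`, `min_len`, `max_len`,
#'   `min_cys`, `constrained` (number of constrained motif positions).
#' @export
load_family_motifs <- function(path = system.file("extdata",
                                                  "family_motifs.yaml",
                                                  package = "npmine")) {
  y <- yaml::read_yaml(path)
  motifs <- lapply(y$families, function(f) {
    m <- list(family = f$family,
              c_pattern = f$c_pattern %||% NULL,
              n_pattern = f$n_pattern %||% NULL,
              requires_amide = f$requires_amide %||% NULL,
              requires_pq = f$requires_pq %||% NULL,
              min_len = f$min_len %||% 1L,
              max_len = f$max_len %||% 1000L,
              min_cys = f$min_cys %||% 0L)
    m$constrained <- .count_constrained(m$c_pattern) +
      .count_constrained(m$n_pattern)
    if (m$constrained < 3L)
      stop(sprintf("motif for family '%s' has fewer than 3 constrained positions",
                   m$family))
    m
  })
  names(motifs) <- vapply(motifs, `[[`, "", "family")
  motifs
}

# count constrained positions of an anchored pattern: a character class or a
# literal residue is one constrained position, '.' is unconstrained
.count_constrained <- function(pattern) {
  if (is.null(pattern)) return(0L)
  p <- gsub("[\\^\\$]", "", pattern)
  n <- 0L
  i <- 1L
  chars <- strsplit(p, "", fixed = TRUE)[[1L]]
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i
      while (chars[j] != "]") j <- j + 1L
      n <- n + 1L
      i <- j + 1L
    } else {
      if (chars[i] != ".") n <- n + 1L
      i <- i + 1L
    }
  }
  n
}

#' Classify a mature peptide by terminal consensus motif
#'
#' Every registry motif is tested for compatibility (length window,
#' amidation and pyroglutamate requirements, cysteine minimum, anchored
#' pattern match); among matches the motif with the most constrained
#' positions wins, ties broken alphabetically by family name.
#'
#' @param peptide a row of the [excise_peptides()] table, or a list/string;
#'   strings in shorthand notation are parsed with
#'   [parse_peptide_notation()].
#' @param registry motif list from [load_family_motifs()].
#' @return List `family`, `evidence = "motif"`, `score` (constrained
#'   positions of the winning motif), `runner_up` (or `NULL`), or `NULL`
#'   when unassigned.
#' @export
classify_by_motif <- function(peptide, registry = load_family_motifs()) {
  if (length(registry) == 0L) stop("empty motif registry")
  if (is.character(peptide)) peptide <- parse_peptide_notation(peptide)
  if (is.data.frame(peptide)) peptide <- as.list(peptide[1L, ])
  s <- peptide$sequence
  len <- nchar(s)
  n_cys <- sum(strsplit(s, "", fixed = TRUE)[[1L]] == "C")
  hits <- list()
  for (m in registry) {
    if (len < m$min_len || len > m$max_len) next
    if (!is.null(m$requires_amide) &&
        isTRUE(m$requires_amide) != isTRUE(peptide$amidated)) next
    if (!is.null(m$requires_pq) &&
        isTRUE(m$requires_pq) != isTRUE(peptide$pyroglutamate)) next
    if (n_cys < m$min_cys) next
    if (!is.null(m$c_pattern) && !grepl(paste0(m$c_pattern, "$"), s)) next
    if (!is.null(m$n_pattern) && !grepl(paste0("^", sub("^\\^", "", m$n_pattern)), s)) next
    hits[[length(hits) + 1L]] <- m
  }
  if (length(hits) == 0L) return(NULL)
  sc <- vapply(hits, `[[`, 0L, "constrained")
  fam <- vapply(hits, `[[`, "", "family")
  o <- order(-sc, fam)
  winner <- hits[[o[1L]]]
  runner <- if (length(hits) > 1L)
    list(family = fam[o[2L]], score = sc[o[2L]]) else NULL
  list(family = winner$family, evidence = "motif",
       score = winner$constrained, runner_up = runner)
}

#' Homology scan of targets against a labelled query set
#'
#' The offline stand-in for a tblastn mining step: every target is scored
#' against every query by Smith-Waterman and inherits the family of its
#' best-scoring query when the score reaches `min_score_ratio` times the
#' query self-score. The per-hit ratio is reported so results can be
#' re-screened manually.
#'
#' @param queries list of [seq_record] with family labels in `desc` (or a
#'   names vector via `query_families`).
#' @param targets list of [seq_record].
#' @param min_score_ratio self-score ratio threshold (default 0.25).
#' @param matrix substitution matrix.
#' @param gap_open,gap_extend affine gap parameters.
#' @param query_families optional character vector of family labels parallel
#'   to `queries` (defaults to the `desc` field).
#' @return data.frame: `target_id`, `family` (NA when below threshold),
#'   `best_query`, `score`, `ratio`, `runner_up_family`, `runner_up_ratio`.
#' @export
homology_scan <- function(queries, targets, min_score_ratio = 0.25,
                          matrix = substitution_matrix("BLOSUM62"),
                          gap_open = 10, gap_extend = 0.5,
                          query_families = NULL) {
  if (length(targets) == 0L)
    return(data.frame(target_id = character(0), family = character(0),
                      best_query = character(0), score = numeric(0),
                      ratio = numeric(0), runner_up_family = character(0),
                      runner_up_ratio = numeric(0)))
  if (is.null(query_families))
    query_families <- vapply(queries, function(q) q$desc, "")
  q_enc <- lapply(queries, function(q) .encode_seq(q$residues, matrix))
  self <- vapply(q_enc, function(e)
    .cpp_sw_score(e, e, matrix, gap_open, gap_extend), 0)
  rows <- lapply(targets, function(t) {
    t_enc <- .encode_seq(t$residues, matrix)
    scores <- vapply(q_enc, function(e)
      .cpp_sw_score(e, t_enc, matrix, gap_open, gap_extend), 0)
    ratios <- scores / self
    # best family = family of the best-ratio query; runner-up from the best
    # query of a *different* family
    o <- order(-ratios, query_families)
    best <- o[1L]
    other <- o[query_families[o] != query_families[best]]
    runner <- if (length(other)) other[1L] else NA_integer_
    data.frame(
      target_id = t$id,
      family = if (ratios[best] >= min_score_ratio) query_families[best]
               else NA_character_,
      best_query = queries[[best]]$id,
      score = scores[best], ratio = ratios[best],
      runner_up_family = if (!is.na(runner)) query_families[runner] else NA_character_,
      runner_up_ratio = if (!is.na(runner)) ratios[runner] else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Published mature-peptide fixture (three parasitoid wasp species)
#'
#' Loads the bundled table of putative mature peptides of
#' *Nasonia vitripennis*, *Fopius arisanus* and *Argochrysis armilla*
#' in shorthand notation, parsed into sequences plus PTM flags.
#'
#' @param path TSV path (default: bundled copy).
#' @return data.frame: `species`, `family`, `notation`, `sequence`,
#'   `amidated`, `pyroglutamate`, `partial`.
#' @export
published_peptides <- function(path = system.file("extdata",
                                                  "table1_peptides.tsv",
                                                  package = "npmine")) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  parsed <- lapply(tab$notation, parse_peptide_notation)
  tab$sequence <- vapply(parsed, `[[`, "", "sequence")
  tab$amidated <- vapply(parsed, `[[`, TRUE, "amidated")
  tab$pyroglutamate <- vapply(parsed, `[[`, TRUE, "pyroglutamate")
  tab$partial <- vapply(parsed, `[[`, TRUE, "partial")
  tab
}
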