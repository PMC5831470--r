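#' Optimal global alignment (Needleman-Wunsch, affine gaps)
#'
#' Defaults mirror the ClustalX slow-accurate protein settings
#' (gap-opening 10, gap-extension 0.1); the substitution matrix is a free
#' parameter (BLOSUM62 default, PAM250 bundled as the classic alternative).
#' Traceback is deterministic (diagonal > up > left).
#'
#' @param a,b protein strings.
#' @param matrix substitution matrix.
#' @param gap_open,gap_extend affine gap parameters; a gap of length L
#'   costs `gap_open + gap_extend * L`.
#' @return An `alignment_set` (list of `members` = named gapped strings,
#'   `length` = number of columns) of the two sequences, with the score in
#'   attribute `score`.
#' @export
global_align <- function(a, b, matrix = substitution_matrix("BLOSUM62"),
                         gap_open = 10, gap_extend = 0.1) {
  if (!nzchar(a) || !nzchar(b)) stop("global_align requires non-empty strings")
  res <- .cpp_pair_align(.encode_seq(a, matrix), .encode_seq(b, matrix),
                         matrix, gap_open, gap_extend, FALSE)
  aln <- alignment_set(c(a = .decode_aln(res$a_aln, matrix),
                         b = .decode_aln(res$b_aln, matrix)))
  attr(aln, "score") <- res$score
  aln
}

#' Construct / validate an alignment set
#'
#' @param members named character vector of equal-length gapped strings.
#' @return `alignment_set` object; all-gap columns are an error.
#' @export
alignment_set <- function(members) {
  if (is.null(names(members)) || any(!nzchar(names(members))))
    names(members) <- paste0("seq", seq_along(members))
  L <- unique(nchar(members))
  if (length(L) != 1L) stop("aligned strings must have equal length")
  m <- .aln_matrix(members)
  if (ncol(m) && any(colSums(m != "-") == 0L)) stop("all-gap column in alignment")
  structure(list(members = members, length = L), class = "alignment_set")
}

.aln_matrix <- function(members) {
  do.call(rbind, strsplit(unname(members), "", fixed = TRUE))
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("<alignment_set: %d sequences x %d columns>\n",
              length(x$members), x$length))
  invisible(x)
}

#' Progressive multiple alignment by the center-star strategy
#'
#' The sequence maximising summed pairwise percent identity against all
#' others is chosen as center (ties broken by identifier order); every other
#' sequence is aligned pairwise to the center with [global_align()] and the
#' pairwise alignments merged under "once a gap, always a gap". The merge
#' order is fixed (sorted identifiers), so permuting the input order changes
#' neither columns nor content; rows are returned in input order.
#'
#' @param seqs named character vector (or list of [seq_record]) of >= 1
#'   protein sequences.
#' @param matrix,gap_open,gap_extend passed to [global_align()].
#' @return An `alignment_set`.
#' @export
progressive_align <- function(seqs, matrix = substitution_matrix("BLOSUM62"),
                              gap_open = 10, gap_extend = 0.1) {
  if (is.list(seqs) && inherits(seqs[[1L]], "seq_record"))
    seqs <- setNames(vapply(seqs, `[[`, "", "residues"),
                     vapply(seqs, `[[`, "", "id"))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  k <- length(seqs)
  if (k == 1L) return(alignment_set(seqs))
  if (k == 2L) {
    aln <- global_align(seqs[[1L]], seqs[[2L]], matrix, gap_open, gap_extend)
    names(aln$members) <- names(seqs)
    return(aln)
  }
  # center = max summed identity (computed on pairwise global alignments)
  ids <- names(seqs)
  total <- setNames(numeric(k), ids)
  for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    pid <- percent_identity(global_align(seqs[[i]], seqs[[j]], matrix,
                                         gap_open, gap_extend),
                            mode = "all_columns")
    total[i] <- total[i] + pid
    total[j] <- total[j] + pid
  }
  center_id <- ids[order(-total, ids)][1L]
  others <- sort(setdiff(ids, center_id))
  # master center string with accumulated gaps; member rows padded in step
  master <- seqs[[center_id]]
  rows <- list()
  rows[[center_id]] <- master
  for (id in others) {
    pa <- global_align(seqs[[center_id]], seqs[[id]], matrix, gap_open,
                       gap_extend)
    c_aln <- strsplit(pa$members[[1L]], "", fixed = TRUE)[[1L]]
    s_aln <- strsplit(pa$members[[2L]], "", fixed = TRUE)[[1L]]
    # merge pairwise (c_aln/s_aln) into master coordinates
    mchars <- strsplit(rows[[center_id]], "", fixed = TRUE)[[1L]]
    mi <- 1L; pi <- 1L
    new_master <- character(0); new_row <- character(0)
    upd <- lapply(rows, function(r) character(0))
    old <- lapply(rows, function(r) strsplit(r, "", fixed = TRUE)[[1L]])
    while (mi <= length(mchars) || pi <= length(c_aln)) {
      m_res <- if (mi <= length(mchars)) mchars[mi] else NA
      p_res <- if (pi <= length(c_aln)) c_aln[pi] else NA
      if (!is.na(m_res) && m_res == "-" && (is.na(p_res) || p_res != "-")) {
        # master-only gap column: pad new sequence
        for (nm in names(upd)) upd[[nm]] <- c(upd[[nm]], old[[nm]][mi])
        new_row <- c(new_row, "-")
        mi <- mi + 1L
      } else if (!is.na(p_res) && p_res == "-") {
        # gap inserted into center by the new pairwise alignment
        for (nm in names(upd)) upd[[nm]] <- c(upd[[nm]], "-")
        new_row <- c(new_row, s_aln[pi])
        pi <- pi + 1L
      } else {
        for (nm in names(upd)) upd[[nm]] <- c(upd[[nm]], old[[nm]][mi])
        new_row <- c(new_row, s_aln[pi])
        mi <- mi + 1L; pi <- pi + 1L
      }
    }
    rows <- lapply(upd, paste, collapse = "")
    rows[[id]] <- paste(new_row, collapse = "")
  }
  alignment_set(unlist(rows[ids]))
}

#' Percent identity of a pairwise alignment
#'
#' @param alignment an `alignment_set` of exactly 2 members.
#' @param mode denominator convention: `"ungapped_columns"` (default;
#'   columns where both sequences carry a residue) or `"all_columns"`.
#' @return Identity in percent.
#' @export
percent_identity <- function(alignment,
                             mode = c("ungapped_columns", "all_columns")) {
  mode <- match.arg(mode)
  if (length(alignment$members) != 2L)
    stop("percent_identity requires a pairwise alignment")
  m <- .aln_matrix(alignment$members)
  both <- m[1L, ] != "-" & m[2L, ] != "-"
  ident <- sum(m[1L, both] == m[2L, both])
  denom <- if (mode == "ungapped_columns") sum(both) else ncol(m)
  if (denom == 0L) stop("zero comparable columns; identity undefined")
  100 * ident / denom
}

#' Per-column conservation shading categories
#'
#' Mirrors the dark/grey shading convention of published alignment figures:
#' `identical` when one residue type fills the column, `high` when the modal
#' residue frequency is >= 0.8 (gaps count in the denominator), else `low`.
#'
#' @param alignment `alignment_set` with >= 2 members.
#' @return Character vector of length `alignment$length` over
#'   `{identical, high, low}`.
#' @export
conservation_shading <- function(alignment) {
  if (length(alignment$members) < 2L)
    stop("conservation shading requires >= 2 sequences")
  m <- .aln_matrix(alignment$members)
  apply(m, 2L, function(col) {
    res <- col[col != "-"]
    if (length(res) == 0L) return("low")
    tab <- table(res)
    top <- max(tab) / length(col)
    if (length(tab) == 1L && length(res) == length(col)) "identical"
    else if (top >= 0.8) "high"
    else "low"
  })
}

#' Sequence-logo profile of an alignment
#'
#' Per-column residue frequencies (gaps excluded from counts) and
#' information content `R_i = log2(20) - (H_i + e_n)` with `H_i` the Shannon
#' entropy of the column and `e_n = 19/(2 ln(2) n)` the small-sample
#' correction (`n` = residues observed in the column); negative corrected
#' values clamp to 0. All-gap columns carry 0 bits and are flagged.
#'
#' @param alignment `alignment_set` (>= 1 member).
#' @param small_sample_correction apply `e_n` (default TRUE).
#' @return List with `freq` (20 x L matrix), `information` (bits per
#'   column), `n_sequences`, `all_gap` (logical per column).
#' @export
sequence_logo <- function(alignment, small_sample_correction = TRUE) {
  m <- .aln_matrix(alignment$members)
  aas <- setdiff(PROTEIN_ALPHABET, c("X", "*"))
  L <- ncol(m)
  freq <- matrix(0, nrow = length(aas), ncol = L, dimnames = list(aas, NULL))
  info <- numeric(L)
  all_gap <- logical(L)
  for (j in seq_len(L)) {
    res <- m[, j]
    res <- res[res %in% aas]
    if (length(res) == 0L) {
      all_gap[j] <- TRUE
      next
    }
    f <- table(factor(res, levels = aas)) / length(res)
    freq[, j] <- as.numeric(f)
    H <- -sum(f[f > 0] * log2(f[f > 0]))
    e_n <- if (small_sample_correction) 19 / (2 * log(2) * length(res)) else 0
    info[j] <- max(0, log2(20) - (H + e_n))
  }
  list(freq = freq, information = info,
       n_sequences = length(alignment$members), all_gap = all_gap)
}

#' C-terminally anchored gapless alignment of short homologous peptides
#'
#' Short family paracopies (for shading and logos) are aligned by right-
#' justification without internal gaps, mirroring the manual alignment of
#' C-terminal consensus motifs.
#'
#' @param seqs named character vector of peptides.
#' @return `alignment_set` padded with leading gaps.
#' @export
cterm_anchor_align <- function(seqs) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  L <- max(nchar(seqs))
  alignment_set(vapply(seqs, function(s)
    paste0(strrep("-", L - nchar(s)), s), "", USE.NAMES = TRUE))
}
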