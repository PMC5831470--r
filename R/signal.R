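# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0, `*` = -4.5)

SMALL_NEUTRAL <- c("A", "G", "S", "C", "T", "V")

#' Predict the signal-peptide cleavage position of a precursor
#'
#' A transparent two-component stand-in for neural-network signal peptide
#' predictors, designed so pipelines can run fully offline. Candidate
#' cleavage positions 10..45 are scanned; each candidate `c` (the length of
#' the putative signal peptide, so the mature chain starts at 0-based index
#' `c`) is scored as
#'
#'   `score = w_h * h + w_c * b - penalties`
#'
#' where `h` is the mean Kyte-Doolittle hydropathy of the best
#' `h_window`-residue window inside positions 3..(c-4) (1-based), rescaled
#' from \[-4.5, 4.5\] to \[0, 1\]; `b` is the (-3,-1)-rule bonus (0.5 for a
#' small neutral residue A/G/S/C/T/V at position -1 and 0.5 at -3 relative
#' to the cleavage site); penalties are 0.3 for a proline at -1..+1 and 0.1
#' per charged residue (D/E/K/R) inside the chosen hydrophobic window. The
#' candidate with the highest score is returned when it reaches `threshold`;
#' the first (most N-terminal) candidate wins ties. Because candidates are
#' bounded at 45, appending residues after position 60 can never change the
#' prediction.
#'
#' @param record protein [seq_record] (or a plain string).
#' @param threshold minimum score to call a signal peptide (default 0.45).
#' @param w_h,w_c weights of the hydrophobicity and (-3,-1) components.
#' @param h_window hydrophobic window width (default 8; shrinks, minimum 4,
#'   for the shortest candidates).
#' @return List with `cleavage_index` (signal length, mature chain starts at
#'   this 0-based index), `score` and `source = "heuristic"`, or `NULL` when
#'   no candidate reaches the threshold or the sequence is shorter than the
#'   25 residues needed to carry a signal peptide plus a mature chain.
#' @export
predict_signal_peptide <- function(record, threshold = 0.45,
                                   w_h = 0.6, w_c = 0.4, h_window = 8L) {
  s <- if (inherits(record, "seq_record")) record$residues else toupper(record)
  n <- nchar(s)
  if (n < 25L) return(NULL)            # too short to carry a signal peptide
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  kd <- unname(KD_SCALE[chars])
  kd[is.na(kd)] <- 0
  best_score <- -Inf
  best_c <- NA_integer_
  for (cand in 10:min(45L, n - 1L)) {
    lo <- 3L                 # 1-based window bounds within the signal
    hi <- cand - 4L
    if (hi - lo + 1L < 4L) next
    w <- min(h_window, hi - lo + 1L)
    # best mean-hydropathy window of width w ending in the h-region just
    # N-terminal of the c-region (ends within [cand-7, cand-4]): the
    # hydrophobic core must abut the cleavage region, which stops distant
    # downstream candidates from re-using it
    ends <- max(lo + w - 1L, cand - 7L):hi
    starts <- pmax(lo, ends - w + 1L)
    means <- vapply(seq_along(ends), function(k)
      mean(kd[starts[k]:ends[k]]), 0)
    wi <- which.max(means)
    h <- (means[wi] + 4.5) / 9
    h <- min(max(h, 0), 1)
    win <- chars[starts[wi]:ends[wi]]
    b <- 0.5 * (chars[cand] %in% SMALL_NEUTRAL) +
      0.5 * (chars[cand - 2L] %in% SMALL_NEUTRAL)
    pen <- 0.3 * any(chars[c(cand, min(cand + 1L, n))] == "P") +
      0.1 * sum(win %in% c("D", "E", "K", "R"))
    score <- w_h * h + w_c * b - pen
    score <- min(max(score, 0), 1)
    if (score > best_score + 1e-12) {
      best_score <- score
      best_c <- cand
    }
  }
  if (!is.finite(best_score) || best_score < threshold) return(NULL)
  list(cleavage_index = best_c, score = best_score, source = "heuristic")
}

#' Load externally computed signal-peptide annotations
#'
#' Bridge for predictions computed with an external tool (e.g. a SignalP
#' run done elsewhere). Entries override the heuristic in
#' [annotate_precursor()].
#'
#' @param path TSV with columns `id`, `cleavage_index`, `score`.
#' @return Named list of signal predictions (`source = "external"`).
#'   Duplicated ids resolve last-wins with a warning; malformed rows are an
#'   error naming the line.
#' @export
load_external_signal_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  if (length(lines) == 0L) return(out)
  start <- 1L
  if (grepl("^id\\b", lines[1L])) start <- 2L
  if (start > length(lines)) return(out)
  for (i in start:length(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L || is.na(suppressWarnings(as.integer(f[2L]))) ||
        is.na(suppressWarnings(as.numeric(f[3L]))))
      stop(sprintf("malformed signal annotation at line %d: '%s'", i, lines[i]))
    id <- f[1L]
    if (!is.null(out[[id]]))
      warning(sprintf("duplicate signal annotation for '%s'; last wins", id))
    out[[id]] <- list(cleavage_index = as.integer(f[2L]),
                      score = as.numeric(f[3L]), source = "external")
  }
  out
}
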