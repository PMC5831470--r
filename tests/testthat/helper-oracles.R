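# Independent oracles used by the property tests. These re-derive expected
# results by direct enumeration and share no code with the implementation.

# ---- brute-force cleavage-rule evaluator -----------------------------------
# Evaluates every position of a propeptide against the default rule table
# independently, then resolves each maximal basic run to its rightmost
# admissible position.
bf_cleavage_sites <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  is_basic <- function(i) i >= 1L && i <= n && ch[i] %in% c("K", "R")
  admissible <- function(i) {
    if (!is_basic(i)) return(NULL)
    prev_basic <- is_basic(i - 1L)
    if (ch[i] == "K" && !prev_basic) return(NULL)  # mono-K never cleaves
    motif <- if (prev_basic) paste0(ch[i - 1L], ch[i]) else "monoR"
    if (motif %in% c("KK", "RK", "monoR")) {
      found <- FALSE
      for (o in c(3L, 5L, 7L)) if (is_basic(i - o)) found <- TRUE
      if (!found) return(NULL)
    }
    if (motif != "KR") {
      for (k in c(i - 2L, i - 1L)) if (k >= 1L && ch[k] == "P") return(NULL)
      if (i + 1L <= n && ch[i + 1L] == "P") return(NULL)
      for (k in (i - 3L):(i + 3L))
        if (k >= 1L && k <= n && ch[k] == "C") return(NULL)
    }
    motif
  }
  out <- list()
  i <- 1L
  while (i <= n) {
    if (!is_basic(i)) { i <- i + 1L; next }
    j <- i
    while (j < n && is_basic(j + 1L)) j <- j + 1L
    for (p in j:i) {
      m <- admissible(p)
      if (!is.null(m)) {
        out[[length(out) + 1L]] <- list(cut_after = p - 1L, motif_class = m)
        break
      }
    }
    i <- j + 1L
  }
  out
}

# ---- exhaustive affine-gap alignment oracle --------------------------------
# Enumerates every global alignment (as an op path over M/U/L moves) and
# scores it directly: substitution scores per M column plus
# -(open + extend * len) per maximal run of U ops and per maximal run of L.
enum_global_score <- function(a, b, mat, open, extend) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, ops) {
    if (i == na && j == nb) {
      best <<- max(best, score_ops(ops, ca, cb, mat, open, extend))
      return(invisible(NULL))
    }
    if (i < na && j < nb) rec(i + 1L, j + 1L, c(ops, "M"))
    if (i < na) rec(i + 1L, j, c(ops, "U"))
    if (j < nb) rec(i, j + 1L, c(ops, "L"))
    invisible(NULL)
  }
  if (na == 0L && nb == 0L) return(0)
  rec(0L, 0L, character(0))
  best
}

score_ops <- function(ops, ca, cb, mat, open, extend) {
  s <- 0; i <- 0L; j <- 0L
  runs <- rle(ops)
  for (k in seq_along(runs$values)) {
    op <- runs$values[k]; len <- runs$lengths[k]
    if (op == "M") {
      for (u in seq_len(len)) {
        i <- i + 1L; j <- j + 1L
        s <- s + mat[ca[i], cb[j]]
      }
    } else {
      s <- s - (open + extend * len)
      if (op == "U") i <- i + len else j <- j + len
    }
  }
  s
}

# Local score: best over all substring pairs (including empty = 0).
enum_local_score <- function(a, b, mat, open, extend) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0
  for (i1 in seq_len(na)) for (j1 in i1:na)
    for (i2 in seq_len(nb)) for (j2 in i2:nb) {
      sc <- enum_global_score(substring(a, i1, j1), substring(b, i2, j2),
                              mat, open, extend)
      best <- max(best, sc)
    }
  best
}

# all strings of length 1..max_len over an alphabet
all_strings <- function(alphabet, max_len) {
  out <- character(0)
  cur <- ""
  for (L in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), L))
    out <- c(out, apply(as.matrix(grid), 1L, paste, collapse = ""))
  }
  out
}

# ---- shared recovery metric for synthetic studies --------------------------
recovery_stats <- function(sim) {
  total <- 0L; rec <- 0L; fam <- 0L
  for (sp in names(sim$species)) for (p in sim$species[[sp]]) {
    ann <- annotate_precursor(p$record)
    tt <- p$truth
    for (r in seq_len(nrow(tt))) {
      total <- total + 1L
      m <- which(ann$peptides$sequence == tt$sequence[r] &
                   ann$peptides$start == tt$start[r])
      if (length(m) &&
          ann$peptides$amidated[m[1L]] == tt$amidated[r] &&
          ann$peptides$pyroglutamate[m[1L]] == tt$pyroglutamate[r]) {
        rec <- rec + 1L
        if (!is.na(ann$peptides$family[m[1L]]) &&
            ann$peptides$family[m[1L]] == tt$family[r])
          fam <- fam + 1L
      }
    }
  }
  list(total = total, recovered = rec, family_correct = fam,
       recovery = rec / total,
       family_accuracy = if (rec > 0) fam / rec else NA_real_)
}
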