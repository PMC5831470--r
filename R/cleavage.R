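#' Default prohormone-convertase cleavage rule set
#'
#' A tiered codification of the mono-/dibasic processing-site conventions
#' used for insect prohormones (Veenstra-style positional rules):
#'
#' * `KR` — always cleave after the R (high confidence, no exclusions);
#' * `RR` — cleave (medium) unless an exclusion fires;
#' * `KK`, `RK` — cleave (low) only when another basic residue (K/R) sits at
#'   -3, -5 or -7 relative to the cleaved residue;
#' * mono-`R` — cleave (medium) under the same -3/-5/-7 basic requirement.
#'
#' Exclusions (all tiers except `KR`): a proline immediately C-terminal of
#' the cut (P1') or within the two residues N-terminal of it, or a cysteine
#' within three residues of the site. Overlapping basic runs resolve to the
#' rightmost admissible site of the run. Mono-K is never a site.
#'
#' The set can be replaced wholesale from a YAML file
#' ([read_cleavage_rules()]) because downstream peptide counts depend on it.
#'
#' @return A `cleavage_rules` list with elements `tiers` (data.frame:
#'   `motif_class`, `needs_upstream_basic`, `confidence`) and `exclusions`
#'   (list: `proline_window_n`, `proline_p1prime`, `cys_radius`,
#'   `exempt = "KR"`).
#' @export
default_cleavage_rules <- function() {
  structure(list(
    tiers = data.frame(
      motif_class = c("KR", "RR", "KK", "RK", "monoR"),
      needs_upstream_basic = c(FALSE, FALSE, TRUE, TRUE, TRUE),
      confidence = c("high", "medium", "low", "low", "medium"),
      stringsAsFactors = FALSE),
    exclusions = list(proline_window_n = 2L, proline_p1prime = TRUE,
                      cys_radius = 3L, exempt = "KR"),
    upstream_offsets = c(-3L, -5L, -7L)
  ), class = "cleavage_rules")
}

#' Read a cleavage rule set from YAML
#'
#' @param path YAML file with `tiers` (list of motif_class,
#'   needs_upstream_basic, confidence), `exclusions` and `upstream_offsets`.
#' @return A `cleavage_rules` object.
#' @export
read_cleavage_rules <- function(path) {
  y <- yaml::read_yaml(path)
  tiers <- do.call(rbind, lapply(y$tiers, function(t)
    data.frame(motif_class = t$motif_class,
               needs_upstream_basic = isTRUE(t$needs_upstream_basic),
               confidence = t$confidence, stringsAsFactors = FALSE)))
  structure(list(
    tiers = tiers,
    exclusions = list(
      proline_window_n = as.integer(y$exclusions$proline_window_n %||% 2L),
      proline_p1prime = !isFALSE(y$exclusions$proline_p1prime),
      cys_radius = as.integer(y$exclusions$cys_radius %||% 3L),
      exempt = y$exclusions$exempt %||% "KR"),
    upstream_offsets = as.integer(unlist(y$upstream_offsets %||% c(-3L, -5L, -7L)))
  ), class = "cleavage_rules")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate one candidate position (1-based index i into chars) against the
# rule table, ignoring run resolution. Returns NULL or list(motif, confidence).
.evaluate_site <- function(chars, i, rules) {
  n <- length(chars)
  res <- chars[i]
  if (!res %in% c("K", "R")) return(NULL)
  prev <- if (i > 1L) chars[i - 1L] else ""
  motif <- if (prev %in% c("K", "R")) paste0(prev, res)
           else if (res == "R") "monoR"
           else return(NULL)                      # mono-K: never a site
  tier <- rules$tiers[rules$tiers$motif_class == motif, ]
  if (nrow(tier) == 0L) return(NULL)
  if (tier$needs_upstream_basic) {
    ups <- i + rules$upstream_offsets
    ups <- ups[ups >= 1L]
    if (!any(chars[ups] %in% c("K", "R"))) return(NULL)
  }
  if (!motif %in% rules$exclusions$exempt) {
    # proline at P1' or within the two residues N-terminal of the cut
    pw <- rules$exclusions$proline_window_n
    npos <- (i - pw):(i - 1L)
    npos <- npos[npos >= 1L]
    if (length(npos) && any(chars[npos] == "P")) return(NULL)
    if (rules$exclusions$proline_p1prime && i < n && chars[i + 1L] == "P")
      return(NULL)
    cr <- rules$exclusions$cys_radius
    cpos <- max(1L, i - cr):min(n, i + cr)
    if (any(chars[cpos] == "C")) return(NULL)
  }
  list(motif_class = motif, confidence = tier$confidence)
}

#' Find prohormone cleavage sites in a propeptide
#'
#' Applies the tiered rule table position by position, then resolves each
#' maximal run of consecutive basic residues to its rightmost admissible
#' site, so e.g. `KRR` yields a single cut after the final R.
#'
#' @param propeptide protein string (the precursor minus its signal peptide).
#' @param rules a `cleavage_rules` object (default [default_cleavage_rules()]).
#' @return List of sites, each `list(cut_after, motif_class, confidence)`
#'   with `cut_after` the 0-based index of the last residue of the basic
#'   signal; sorted ascending. Empty propeptide gives an empty list.
#' @export
find_cleavage_sites <- function(propeptide, rules = default_cleavage_rules()) {
  if (is.null(propeptide) || !nzchar(propeptide)) return(list())
  chars <- strsplit(toupper(propeptide), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  basic <- chars %in% c("K", "R")
  # maximal runs of basic residues
  sites <- list()
  i <- 1L
  while (i <= n) {
    if (!basic[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && basic[j + 1L]) j <- j + 1L
    # rightmost admissible position within run [i, j]
    for (p in rev(seq.int(i, j))) {
      hit <- .evaluate_site(chars, p, rules)
      if (!is.null(hit)) {
        sites[[length(sites) + 1L]] <- list(cut_after = p - 1L,
                                            motif_class = hit$motif_class,
                                            confidence = hit$confidence)
        break
      }
    }
    i <- j + 1L
  }
  sites[order(vapply(sites, function(s) s$cut_after, 0L))]
}

ACIDIC <- c("D", "E")

#' Excise mature peptides from a precursor given cleavage sites
#'
#' Fragments between consecutive cuts (and the chain termini) are
#' post-processed in the order carboxypeptidase-style trimming of the
#' trailing K/R run, removal of a terminal amidation-donor glycine
#' (setting `amidated`), and flagging of an N-terminal glutamine as
#' pyroglutamate. Fragments shorter than `min_len` or with an acidic (D/E)
#' fraction above `acidic_fraction` are tagged spacers and excluded.
#'
#' @param precursor [seq_record] or plain protein string.
#' @param signal signal prediction (list with `cleavage_index`) or `NULL`;
#'   when `NULL` the whole chain is treated as propeptide and the first
#'   fragment is flagged `partial`.
#' @param sites list of cleavage sites from [find_cleavage_sites()], with
#'   coordinates relative to the propeptide.
#' @param min_len minimum mature-peptide length (default 4).
#' @param acidic_fraction spacer threshold on the D/E fraction (default 0.5,
#'   exclusive).
#' @return data.frame with one row per mature peptide: `sequence`, `start`,
#'   `end` (0-based half-open, in precursor coordinates, spanning the
#'   processed sequence), `amidated`, `pyroglutamate`, `n_cys`,
#'   `n_disulfides`, `odd_cys`, `partial`. Attribute `spacers` holds the
#'   excluded fragments (data.frame `sequence`, `start`, `end`).
#' @export
excise_peptides <- function(precursor, signal = NULL, sites = list(),
                            min_len = 4L, acidic_fraction = 0.5) {
  s <- if (inherits(precursor, "seq_record")) precursor$residues
       else toupper(precursor)
  n <- nchar(s)
  off <- if (!is.null(signal)) signal$cleavage_index else 0L
  if (off > n) stop("signal cleavage index outside precursor")
  prop <- substring(s, off + 1L, n)
  np <- nchar(prop)
  cuts <- vapply(sites, function(x) x$cut_after, 0L)
  if (length(cuts) && (any(cuts < 0L) || any(cuts >= np)))
    stop("cleavage site outside propeptide")
  bounds <- c(0L, sort(cuts) + 1L, np)      # fragment k: (bounds[k], bounds[k+1]]
  bounds <- unique(bounds)
  peps <- list()
  spacers <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    f_start <- bounds[k]                    # 0-based, propeptide coords
    f_end <- bounds[k + 1L]
    frag <- substring(prop, f_start + 1L, f_end)
    # trim trailing basic run (the cleavage signal + carboxypeptidase step)
    trimmed <- sub("[KR]+$", "", frag)
    amid <- FALSE
    if (endsWith(trimmed, "G") && nchar(trimmed) > 1L) {
      # amide donor only when the G abuts a cleavage signal or the chain end
      if (nchar(trimmed) < nchar(frag) || f_end == np) {
        trimmed <- substring(trimmed, 1L, nchar(trimmed) - 1L)
        amid <- TRUE
      }
    }
    if (!nzchar(trimmed)) next
    chars <- strsplit(trimmed, "", fixed = TRUE)[[1L]]
    p_start <- off + f_start                # precursor coords, 0-based
    p_end <- p_start + length(chars)        # half-open
    acid_frac <- mean(chars %in% ACIDIC)
    if (length(chars) < min_len || acid_frac > acidic_fraction) {
      spacers[[length(spacers) + 1L]] <- data.frame(
        sequence = trimmed, start = p_start, end = p_end,
        stringsAsFactors = FALSE)
      next
    }
    pq <- chars[1L] == "Q"
    census <- cysteine_census(trimmed)
    peps[[length(peps) + 1L]] <- data.frame(
      sequence = trimmed, start = p_start, end = p_end,
      amidated = amid, pyroglutamate = pq,
      n_cys = length(census$cys_positions_from_C),
      n_disulfides = census$n_disulfides,
      odd_cys = census$odd_cys,
      partial = is.null(signal) && k == 1L,
      stringsAsFactors = FALSE)
  }
  out <- if (length(peps)) do.call(rbind, peps) else
    data.frame(sequence = character(0), start = integer(0), end = integer(0),
               amidated = logical(0), pyroglutamate = logical(0),
               n_cys = integer(0), n_disulfides = integer(0),
               odd_cys = logical(0), partial = logical(0))
  attr(out, "spacers") <- if (length(spacers)) do.call(rbind, spacers) else
    data.frame(sequence = character(0), start = integer(0), end = integer(0))
  out
}

#' Cysteine census of a processed peptide
#'
#' Cysteine positions are reported from the C-terminus with the final
#' residue at -1 (the convention used for C-type allatostatins, whose
#' disulfide bridge links the cysteines at -2 and -9). The number of
#' bridges is `n_cys/2` for even counts; odd counts are flagged, never
#' paired, and pairing topology is not assigned.
#'
#' @param peptide processed peptide string (or a row of the excision table).
#' @return List `cys_positions_from_C` (negative integers, ascending) and
#'   `n_disulfides`, plus `odd_cys` flag.
#' @export
cysteine_census <- function(peptide) {
  s <- if (is.data.frame(peptide)) peptide$sequence[1L] else peptide
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  pos <- which(chars == "C") - length(chars) - 1L
  n <- length(pos)
  list(cys_positions_from_C = pos,
       n_disulfides = n %/% 2L,
       odd_cys = n %% 2L == 1L)
}
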