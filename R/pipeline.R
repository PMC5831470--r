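#' Annotate one precursor candidate
#'
#' Chains signal-peptide prediction (or an external override), cleavage-site
#' calling on the propeptide, mature-peptide excision and per-peptide motif
#' classification. The precursor-level family is the modal peptide family
#' (ties broken alphabetically), optionally reconciled with a
#' homology-derived label: agreement upgrades the evidence to `"both"`,
#' disagreement keeps the motif label and records the homology label as
#' runner-up.
#'
#' @param record protein [seq_record].
#' @param rules cleavage rule set.
#' @param motifs motif registry.
#' @param signal_override optional external signal prediction for this id.
#' @param homology_family optional family label from [homology_scan()].
#' @param species,superfamily provenance labels carried into reports.
#' @param signal_threshold,min_len,acidic_fraction tunables surfaced from
#'   the pipeline config.
#' @return Annotated precursor: list with `record`, `species`,
#'   `superfamily`, `signal`, `sites`, `peptides` (excision table plus
#'   `family` column), `family`, `evidence`.
#' @export
annotate_precursor <- function(record, rules = default_cleavage_rules(),
                               motifs = load_family_motifs(),
                               signal_override = NULL,
                               homology_family = NULL,
                               species = "NA", superfamily = "NA",
                               signal_threshold = 0.45,
                               min_len = 4L, acidic_fraction = 0.5) {
  signal <- if (!is.null(signal_override)) signal_override
            else predict_signal_peptide(record, threshold = signal_threshold)
  off <- if (!is.null(signal)) signal$cleavage_index else 0L
  prop <- substring(record$residues, off + 1L)
  sites <- find_cleavage_sites(prop, rules)
  peptides <- excise_peptides(record, signal, sites,
                              min_len = min_len,
                              acidic_fraction = acidic_fraction)
  # report cleavage sites in precursor coordinates
  sites <- lapply(sites, function(s) {
    s$cut_after <- s$cut_after + off
    s
  })
  fams <- character(nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    hit <- classify_by_motif(peptides[i, ], motifs)
    fams[i] <- if (is.null(hit)) NA_character_ else hit$family
  }
  peptides$family <- fams
  family <- NA_character_
  evidence <- NA_character_
  assigned <- fams[!is.na(fams)]
  if (length(assigned)) {
    tab <- sort(table(assigned), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    family <- sort(top)[1L]
    evidence <- "motif"
  }
  if (!is.null(homology_family) && !is.na(homology_family)) {
    if (is.na(family)) {
      family <- homology_family
      evidence <- "homology"
    } else if (identical(family, homology_family)) {
      evidence <- "both"
    }
  }
  list(record = record, species = species, superfamily = superfamily,
       signal = signal, sites = sites, peptides = peptides,
       family = family, evidence = evidence)
}

#' Presence/paracopy summary across species
#'
#' @param peptides data.frame with columns `species`, `family`,
#'   `precursor_id`, `sequence` (one row per classified mature peptide).
#' @return List of matrices (families x species): `presence` (logical),
#'   `precursors` (distinct precursor records), `paracopies` (distinct
#'   mature peptide sequences).
#' @export
summarize_presence <- function(peptides) {
  if (nrow(peptides) == 0L)
    return(list(presence = matrix(FALSE, 0, 0),
                precursors = matrix(0L, 0, 0),
                paracopies = matrix(0L, 0, 0)))
  peptides <- peptides[!is.na(peptides$family), , drop = FALSE]
  fams <- sort(unique(peptides$family))
  sps <- sort(unique(peptides$species))
  prec <- matrix(0L, length(fams), length(sps), dimnames = list(fams, sps))
  para <- prec
  for (f in fams) for (s in sps) {
    sel <- peptides$family == f & peptides$species == s
    prec[f, s] <- length(unique(peptides$precursor_id[sel]))
    para[f, s] <- length(unique(peptides$sequence[sel]))
  }
  list(presence = prec >= 1L, precursors = prec, paracopies = para)
}

.stage_log <- function(log, stage, n_in, n_out, note = "") {
  line <- sprintf("stage=%s records_in=%d records_out=%d %s",
                  stage, n_in, n_out, note)
  message(line)
  c(log, line)
}

#' Run the annotation pipeline end-to-end
#'
#' Stages: read (six-frame translating nucleotide inputs) -> homology scan
#' against the labelled query set (optional) -> signal prediction ->
#' cleavage + excision -> motif classification -> per-family comparative
#' outputs (C-terminally anchored logo and shading tables) -> per-family
#' NJ phylogeny with bootstrap (families observed in >= 4 species) ->
#' presence/paracopy summary. Every stage's output is written under
#' `out_dir` and recorded with a checksum in `MANIFEST.tsv`; reruns with
#' the same config and seed are byte-identical.
#'
#' @param config path to a YAML file or an equivalent list. Keys:
#'   `inputs` (list of `species`/`path`/`alphabet` entries), optional
#'   `superfamily` per input, optional `queries` (labelled FASTA,
#'   family taken from the description), optional `signal_overrides` (TSV),
#'   `out` (output directory), `seed`, and tunables `signal.threshold`,
#'   `prohormone.min_len`, `prohormone.acidic_fraction`,
#'   `homology.min_score_ratio`, `phylo.replicates`, optional
#'   `cleavage_rules` (YAML path), `motifs` (YAML path).
#' @param out_dir overrides `config$out`.
#' @return Invisibly: list with `annotated`, `peptides`, `summary`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- out_dir %||% config$out %||% stop("config must name an output dir")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  thr <- config$signal.threshold %||% 0.45
  min_len <- config$prohormone.min_len %||% 4L
  acid <- config$prohormone.acidic_fraction %||% 0.5
  ratio <- config$homology.min_score_ratio %||% 0.25
  reps <- config$phylo.replicates %||% 100L
  rules <- if (!is.null(config$cleavage_rules))
    read_cleavage_rules(config$cleavage_rules) else default_cleavage_rules()
  motifs <- if (!is.null(config$motifs))
    load_family_motifs(config$motifs) else load_family_motifs()
  overrides <- if (!is.null(config$signal_overrides))
    load_external_signal_annotations(config$signal_overrides) else list()
  log <- character(0)
  manifest <- list()
  add_manifest <- function(stage, path, n) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(path), n_records = n,
      checksum_md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }

  # --- read + translate ------------------------------------------------
  records <- list()
  for (inp in config$inputs) {
    if (is.null(inp$path) || !file.exists(inp$path))
      stop(sprintf("missing input file: %s", inp$path %||% "<unnamed>"))
    alpha <- inp$alphabet %||% "protein"
    recs <- read_fasta(inp$path, alpha)
    if (alpha == "nucleotide")
      recs <- unlist(lapply(recs, six_frame_translate), recursive = FALSE)
    recs <- Filter(function(r) nzchar(r$residues), recs)
    for (r in recs) {
      records[[length(records) + 1L]] <- list(
        record = r, species = inp$species %||% "NA",
        superfamily = inp$superfamily %||% "NA")
    }
  }
  log <- .stage_log(log, "read", length(config$inputs), length(records))
  if (length(records) == 0L) stop("no candidate records after read stage")

  # --- homology scan ----------------------------------------------------
  hom <- NULL
  if (!is.null(config$queries)) {
    queries <- read_fasta(config$queries, "protein")
    hom <- homology_scan(queries, lapply(records, `[[`, "record"),
                         min_score_ratio = ratio)
    scan_path <- file.path(out, "homology_scan.tsv")
    write.table(hom, scan_path, sep = "\t", quote = FALSE, row.names = FALSE)
    add_manifest("homology_scan", scan_path, nrow(hom))
    log <- .stage_log(log, "homology_scan", length(records),
                      sum(!is.na(hom$family)))
  }

  # --- annotate ---------------------------------------------------------
  annotated <- lapply(records, function(entry) {
    id <- entry$record$id
    hom_fam <- if (!is.null(hom)) hom$family[match(id, hom$target_id)] else NULL
    annotate_precursor(entry$record, rules, motifs,
                       signal_override = overrides[[id]],
                       homology_family = hom_fam,
                       species = entry$species,
                       superfamily = entry$superfamily,
                       signal_threshold = thr, min_len = min_len,
                       acidic_fraction = acid)
  })
  report <- write_annotation_report(annotated, file.path(out, "annotation"))
  pep_tab <- do.call(rbind, lapply(annotated, function(a) {
    if (nrow(a$peptides) == 0L) return(NULL)
    cbind(species = a$species, precursor_id = a$record$id,
          a$peptides, stringsAsFactors = FALSE)
  }))
  if (is.null(pep_tab))
    pep_tab <- data.frame(species = character(0), precursor_id = character(0),
                          sequence = character(0), family = character(0))
  add_manifest("annotate", report[["report"]], length(annotated))
  add_manifest("peptides", report[["table"]], nrow(pep_tab))
  log <- .stage_log(log, "annotate", length(records), nrow(pep_tab))

  # --- per-family comparative outputs ----------------------------------
  fams <- sort(unique(pep_tab$family[!is.na(pep_tab$family)]))
  comp_rows <- list()
  for (f in fams) {
    seqs <- pep_tab$sequence[!is.na(pep_tab$family) & pep_tab$family == f]
    seqs <- unique(seqs)
    if (length(seqs) < 2L) next
    names(seqs) <- paste0(f, "_", seq_along(seqs))
    aln <- cterm_anchor_align(seqs)
    logo <- sequence_logo(aln)
    shade <- conservation_shading(aln)
    comp_rows[[f]] <- data.frame(
      family = f, column = seq_len(aln$length),
      information_bits = round(logo$information, 4),
      shading = shade, stringsAsFactors = FALSE)
  }
  if (length(comp_rows)) {
    comp_path <- file.path(out, "family_profiles.tsv")
    comp <- do.call(rbind, comp_rows)
    write.table(comp, comp_path, sep = "\t", quote = FALSE, row.names = FALSE)
    add_manifest("comparative", comp_path, nrow(comp))
    log <- .stage_log(log, "comparative", length(fams), length(comp_rows))
  }

  # --- per-family phylogeny --------------------------------------------
  tree_n <- 0L
  for (f in fams) {
    sel <- vapply(annotated, function(a)
      identical(a$family, f), TRUE)
    entries <- annotated[sel]
    sps <- vapply(entries, `[[`, "", "species")
    keep <- !duplicated(sps)
    entries <- entries[keep]
    if (length(entries) < 4L) next
    seqs <- setNames(vapply(entries, function(a) a$record$residues, ""),
                     vapply(entries, function(a) a$species, ""))
    aln <- progressive_align(seqs)
    tr <- bootstrap_support(aln, replicates = reps, seed = seed)
    tree_path <- file.path(out, paste0("tree_", gsub("[^A-Za-z0-9]", "_", f),
                                       ".nwk"))
    write_newick(tr, tree_path)
    add_manifest("phylo", tree_path, length(entries))
    tree_n <- tree_n + 1L
  }
  if (tree_n) log <- .stage_log(log, "phylo", length(fams), tree_n)

  # --- presence summary -------------------------------------------------
  summary <- summarize_presence(pep_tab)
  if (nrow(summary$precursors)) {
    pres_path <- file.path(out, "presence_matrix.tsv")
    pres <- data.frame(family = rownames(summary$precursors),
                       summary$precursors, check.names = FALSE)
    write.table(pres, pres_path, sep = "\t", quote = FALSE, row.names = FALSE)
    para_path <- file.path(out, "paracopy_matrix.tsv")
    para <- data.frame(family = rownames(summary$paracopies),
                       summary$paracopies, check.names = FALSE)
    write.table(para, para_path, sep = "\t", quote = FALSE, row.names = FALSE)
    add_manifest("summarize", pres_path, nrow(pres))
    add_manifest("summarize", para_path, nrow(para))
    log <- .stage_log(log, "summarize", nrow(pep_tab), nrow(pres))
  }

  log_path <- file.path(out, "pipeline.log")
  writeLines(log, log_path)
  man <- do.call(rbind, manifest)
  write.table(man, file.path(out, "MANIFEST.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(annotated = annotated, peptides = pep_tab,
                 summary = summary, manifest = man))
}
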