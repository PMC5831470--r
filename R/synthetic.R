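# Replacement alphabet for template variation and tree evolution: K/R/C/P are
# excluded so that substitutions never fabricate cleavage signals, disulfide
# chemistry or proline exclusions, while substitutions can still *destroy*
# true signals (the realistic failure mode the recovery gates budget for).
MUTATION_ALPHABET <- c("A", "D", "E", "F", "G", "H", "I", "L", "M", "N",
                       "Q", "S", "T", "V", "W", "Y")

#' Default synthetic family templates
#'
#' Seven neuropeptide families whose mature regions are cleavage-clean
#' under the default rule table when embedded between a flanking `KR` and
#' their allowed C-terminal signals (checked against the tier table; e.g.
#' CCAP admits only `KR` because its C-terminal cysteine triggers the
#' cysteine exclusion for any other tier, and sNPF-like RLRFamide motifs
#' are excluded altogether because their internal arginines form admissible
#' mono-R sites). `variable` lists 1-based positions free to vary between
#' paracopies and species; all other positions (consensus motifs, the
#' pyroglutamate Q, rule-critical residues) are frozen.
#'
#' @return Named list of family templates: `family`, `sequence`,
#'   `amidated`, `pyroglutamate`, `variable`, `signals` (allowed cleavage
#'   signal classes), `n_copies`.
#' @export
default_family_templates <- function() {
  list(
    CCAP = list(family = "CCAP", sequence = "PFCNAFTGC", amidated = TRUE,
                pyroglutamate = FALSE, variable = c(1L, 2L),
                signals = "KR", n_copies = 1L),
    AKH = list(family = "AKH", sequence = "QLNFSTGW", amidated = TRUE,
               pyroglutamate = TRUE, variable = c(2L, 3L, 4L),
               signals = c("KR", "RR"), n_copies = 1L),
    FMRFa = list(family = "FMRFa", sequence = "SSSSGGNLGSSFIRY",
                 amidated = TRUE, pyroglutamate = FALSE,
                 variable = c(1L, 2L, 3L, 4L, 7L, 9L, 10L, 11L),
                 signals = c("KR", "RR", "monoR"), n_copies = 2L),
    TK = list(family = "TK", sequence = "APMGFQGMR", amidated = TRUE,
              pyroglutamate = FALSE, variable = c(1L, 2L, 3L, 5L, 6L),
              signals = c("KR", "RR", "KK"), n_copies = 5L),
    MS = list(family = "MS", sequence = "QDVDHVFLRF", amidated = TRUE,
              pyroglutamate = TRUE, variable = c(2L, 3L, 4L, 5L, 6L),
              signals = c("KR", "RR", "monoR"), n_copies = 1L),
    kinin = list(family = "kinin", sequence = "PFNSWG", amidated = TRUE,
                 pyroglutamate = FALSE, variable = c(2L, 3L),
                 signals = c("KR", "RR"), n_copies = 2L),
    `AST-CCC` = list(family = "AST-CCC", sequence = "NYWRQCAFNAVSCF",
                     amidated = FALSE, pyroglutamate = FALSE,
                     variable = c(1L, 2L, 7L),
                     signals = "KR", n_copies = 1L)
  )
}

# mixture over cleavage-signal classes; renormalised over a template's
# allowed set so every rule tier is exercised across the default families
SIGNAL_MIXTURE <- c(KR = 0.70, RR = 0.15, monoR = 0.10, KK = 0.05)
SIGNAL_STRINGS <- c(KR = "KR", RR = "RR", monoR = "R", KK = "KK")

#' Synthetic study configuration
#'
#' Bundles the generator parameters: family templates, number of species,
#' the species tree (three shallow cherries by default, mirroring the high
#' precursor conservation expected among closely related taxa), the per-site
#' substitution rate, spacer length range and the mandatory seed.
#'
#' @param families template list (default [default_family_templates()]).
#' @param n_species number of species (default 6; must match the tree).
#' @param species_tree Newick string or `phylo`.
#' @param substitution_rate per site per unit branch length (default 0.02).
#' @param n_per_family precursors per family per species (default 1).
#' @param spacer_length_range inter-peptide spacer lengths (default 4..10).
#' @param seed RNG seed (mandatory).
#' @return `synthetic_config` list.
#' @export
synthetic_config <- function(families = default_family_templates(),
                             n_species = 6L,
                             species_tree = NULL,
                             substitution_rate = 0.02,
                             n_per_family = 1L,
                             spacer_length_range = c(4L, 10L),
                             seed) {
  if (missing(seed)) stop("synthetic_config requires an explicit seed")
  if (is.character(families)) {
    known <- default_family_templates()
    bad <- setdiff(families, names(known))
    if (length(bad))
      stop(sprintf("unknown family name(s): %s; known families: %s",
                   paste(bad, collapse = ", "),
                   paste(names(known), collapse = ", ")))
    families <- known[families]
  }
  if (is.null(species_tree))
    species_tree <- paste0("((s1:0.1,s2:0.1):0.08,(s3:0.1,s4:0.1):0.08,",
                           "(s5:0.1,s6:0.1):0.08);")
  tree <- if (inherits(species_tree, "phylo")) species_tree
          else ape::read.tree(text = species_tree)
  if (length(tree$tip.label) != n_species)
    stop("species tree tip count does not match n_species")
  if (substitution_rate < 0) stop("substitution_rate must be >= 0")
  structure(list(families = families, n_species = n_species,
                 species_tree = tree,
                 substitution_rate = substitution_rate,
                 n_per_family = as.integer(n_per_family),
                 spacer_length_range = as.integer(spacer_length_range),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.rand_signal_peptide <- function() {
  n_len <- sample(2:4, 1L)
  core_len <- sample(8:11, 1L)
  paste0("M",
         paste(sample(c("K", "N", "S", "T"), n_len, TRUE), collapse = ""),
         paste(sample(c("L", "I", "F", "M"), core_len, TRUE), collapse = ""),
         sample(c("A", "G", "S"), 1L),
         sample(c("S", "T", "N", "Q", "L", "H"), 1L),
         sample(c("A", "G", "S"), 1L))
}

.rand_spacer <- function(range) {
  len <- sample(range[1L]:range[2L], 1L)
  n_acid <- len %/% 2L + 1L               # strictly > 50% acidic
  chars <- c(sample(c("D", "E"), n_acid, TRUE),
             sample(c("S", "N", "A"), len - n_acid, TRUE))
  paste(sample(chars), collapse = "")
}

.mutate_positions <- function(chars, positions, p) {
  hit <- positions[runif(length(positions)) < p]
  if (length(hit))
    chars[hit] <- sample(MUTATION_ALPHABET, length(hit), TRUE)
  chars
}

#' Generate one synthetic precursor from a family template
#'
#' Architecture: signal peptide (hydrophobic core, small residues at the
#' -3/-1 positions), then for each paracopy an acidic spacer closed by `KR`,
#' the mature peptide (template with its variable positions resampled), an
#' amidation donor G where the family is amidated, and a cleavage signal
#' drawn from the template's allowed classes under the
#' KR 70% / RR 15% / mono-R 10% / KK 5% mixture; a terminal acidic spacer
#' closes the chain. Uses the current RNG state; seed management belongs to
#' the caller.
#'
#' @param template one entry of [default_family_templates()].
#' @param id precursor identifier.
#' @param spacer_length_range integer length-2 vector.
#' @param variation_prob probability that a variable template position is
#'   resampled in a given paracopy (default 0.3).
#' @return List `record` ([seq_record]), `truth` (data.frame: one row per
#'   embedded peptide with processed sequence, 0-based half-open precursor
#'   coordinates, flags), `signal_length`, `frozen` (0-based positions never
#'   substituted during evolution).
#' @export
generate_precursor <- function(template, id = template$family,
                               spacer_length_range = c(4L, 10L),
                               variation_prob = 0.3) {
  sig <- .rand_signal_peptide()
  parts <- sig
  pos <- nchar(sig)                       # 0-based length so far
  frozen <- integer(0)
  truth <- list()
  tchars0 <- strsplit(template$sequence, "", fixed = TRUE)[[1L]]
  frozen_rel <- setdiff(seq_along(tchars0), template$variable)
  weights <- SIGNAL_MIXTURE[template$signals]
  weights <- weights / sum(weights)
  for (copy in seq_len(template$n_copies)) {
    spacer <- .rand_spacer(spacer_length_range)
    parts <- c(parts, spacer, "KR")
    pos <- pos + nchar(spacer) + 2L
    tchars <- tchars0
    vary <- template$variable[runif(length(template$variable)) < variation_prob]
    if (length(vary))
      tchars[vary] <- sample(MUTATION_ALPHABET, length(vary), TRUE)
    pep <- paste(tchars, collapse = "")
    pep_start <- pos
    parts <- c(parts, pep)
    frozen <- c(frozen, pep_start + frozen_rel - 1L)
    pos <- pos + nchar(pep)
    if (template$amidated) {
      parts <- c(parts, "G")
      pos <- pos + 1L
    }
    sig_class <- sample(names(weights), 1L, prob = weights)
    sig_str <- SIGNAL_STRINGS[[sig_class]]
    parts <- c(parts, sig_str)
    pos <- pos + nchar(sig_str)
    truth[[copy]] <- data.frame(
      sequence = pep, start = pep_start, end = pep_start + nchar(pep),
      amidated = template$amidated,
      pyroglutamate = template$pyroglutamate,
      family = template$family, signal_class = sig_class,
      stringsAsFactors = FALSE)
  }
  terminal <- .rand_spacer(spacer_length_range)
  parts <- c(parts, terminal)
  seqstr <- paste(parts, collapse = "")
  list(record = seq_record(id, seqstr, "protein",
                           desc = sprintf("synthetic %s precursor",
                                          template$family)),
       truth = do.call(rbind, truth),
       signal_length = nchar(sig),
       frozen = sort(frozen))
}

#' Evolve root precursors along a species tree
#'
#' Each site substitutes independently on each branch with probability
#' `1 - exp(-rate * branch_length)`; replacements are uniform over a
#' 16-residue alphabet (no K/R/C/P, see [default_family_templates()]);
#' frozen (consensus-motif) positions never substitute. Coordinates are
#' preserved (no indel process), so truth peptide sequences are re-read
#' from the evolved chains with flags inherited from the root.
#'
#' @param root list of precursors from [generate_precursor()].
#' @param tree `phylo` species tree with branch lengths.
#' @param rate substitution rate per site per unit branch length.
#' @param seed RNG seed.
#' @return List per species (named by tip label): list of evolved
#'   precursors, each with `record`, `truth`, `signal_length`.
#' @export
evolve_along_tree <- function(root, tree, rate, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  root_node <- n_tip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  out <- vector("list", n_tip)
  names(out) <- tree$tip.label
  root_states <- lapply(root, function(p)
    strsplit(p$record$residues, "", fixed = TRUE)[[1L]])
  recurse <- function(node, states) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) {   # tip
      sp <- tree$tip.label[node]
      out[[sp]] <<- lapply(seq_along(root), function(k) {
        p <- root[[k]]
        seqstr <- paste(states[[k]], collapse = "")
        truth <- p$truth
        truth$sequence <- vapply(seq_len(nrow(truth)), function(r)
          substring(seqstr, truth$start[r] + 1L, truth$end[r]), "")
        truth$species <- sp
        rec <- seq_record(paste0(sp, "_", p$record$id), seqstr, "protein",
                          desc = p$record$desc)
        list(record = rec, truth = truth, signal_length = p$signal_length,
             frozen = p$frozen)
      })
      return(invisible(NULL))
    }
    for (e in kids) {
      child <- tree$edge[e, 2L]
      bl <- tree$edge.length[e]
      p_sub <- 1 - exp(-rate * bl)
      new_states <- lapply(seq_along(states), function(k) {
        free <- setdiff(seq_along(states[[k]]), root[[k]]$frozen + 1L)
        .mutate_positions(states[[k]], free, p_sub)
      })
      recurse(child, new_states)
    }
    invisible(NULL)
  }
  recurse(root_node, root_states)
  out
}

#' Generate a full synthetic study and write fixtures
#'
#' Draws root precursors (one per family template, times `n_per_family`),
#' evolves them along the species tree and writes one protein FASTA per
#' species, a truth TSV (seqio report schema plus truth columns) and the
#' species tree as Newick.
#'
#' @param config [synthetic_config()].
#' @param out_dir output directory.
#' @param force overwrite a non-empty directory (default FALSE).
#' @return Invisibly, a list with `species` (per-species precursor lists),
#'   `truth` (combined data.frame), `tree`, and the file paths.
#' @export
emit_fixtures <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force)
    stop(sprintf("output directory '%s' is not empty (use force = TRUE)",
                 out_dir))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_study(config)
  paths <- character(0)
  for (sp in names(sim$species)) {
    f <- file.path(out_dir, paste0(sp, ".fasta"))
    write_fasta(lapply(sim$species[[sp]], `[[`, "record"), f)
    paths <- c(paths, f)
  }
  truth_path <- file.path(out_dir, "truth.tsv")
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, truth_path)
  if (config$n_species > 1L) {
    tree_path <- file.path(out_dir, "species_tree.nwk")
    write_newick(config$species_tree, tree_path)
    paths <- c(paths, tree_path)
  } else {
    warning("single species: no tree emitted")
  }
  invisible(c(sim, list(paths = paths)))
}

#' Run the synthetic generator in memory
#'
#' @param config [synthetic_config()].
#' @return List `species` (per-species lists of precursors with truth),
#'   `truth` (combined data.frame incl. signal lengths), `tree`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  bad <- vapply(config$families, function(f) is.null(f$sequence), TRUE)
  if (any(bad))
    stop(sprintf("unknown/invalid family template(s): %s; known: %s",
                 paste(names(config$families)[bad], collapse = ", "),
                 paste(names(default_family_templates()), collapse = ", ")))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  root <- list()
  for (rep in seq_len(config$n_per_family)) {
    for (fam in names(config$families)) {
      tpl <- config$families[[fam]]
      id <- if (config$n_per_family > 1L)
        sprintf("%s_p%d", tpl$family, rep) else tpl$family
      root[[id]] <- generate_precursor(tpl, id, config$spacer_length_range)
    }
  }
  species <- evolve_along_tree(root, config$species_tree,
                               config$substitution_rate,
                               seed = config$seed + 1L)
  truth <- do.call(rbind, lapply(names(species), function(sp) {
    do.call(rbind, lapply(species[[sp]], function(p) {
      t <- p$truth
      t$precursor_id <- p$record$id
      t$signal_length <- p$signal_length
      t
    }))
  }))
  list(species = species, truth = truth, tree = config$species_tree)
}
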