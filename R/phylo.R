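#' Pairwise p-distance matrix of an alignment
#'
#' `d(i,j)` = mismatches / compared columns with pairwise deletion of
#' columns where either sequence is gapped.
#'
#' @param alignment `alignment_set` with >= 3 members.
#' @param model `"p"` (default) or `"poisson"`
#'   (`-log(1 - p)` correction, for distantly related precursors).
#' @return Symmetric numeric matrix with zero diagonal and taxa dimnames.
#' @export
p_distance <- function(alignment, model = c("p", "poisson")) {
  model <- match.arg(model)
  m <- .aln_matrix(alignment$members)
  taxa <- names(alignment$members)
  k <- nrow(m)
  if (k < 3L) stop("p_distance requires >= 3 sequences")
  d <- matrix(0, k, k, dimnames = list(taxa, taxa))
  for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    both <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(both))
      stop(sprintf("no comparable columns between '%s' and '%s'",
                   taxa[i], taxa[j]))
    p <- mean(m[i, both] != m[j, both])
    if (model == "poisson") {
      if (p >= 1) stop("poisson correction undefined at p >= 1")
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration: at each step join the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - S_i - S_j` (row sums `S`), with ties broken by
#' the lexicographically smallest taxon-label pair; branch lengths from the
#' standard two-point formulas, negative estimates clamped to zero with the
#' deficit shifted to the sister branch.
#'
#' @param d symmetric distance matrix (>= 3 taxa, zero diagonal).
#' @return Unrooted [ape] `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (is.data.frame(d)) d <- as.matrix(d)
  n0 <- nrow(d)
  if (n0 < 3L) stop("nj_tree requires >= 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n0)
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  labels <- rownames(d)
  # node bookkeeping: tips 1..n0, internal nodes appended
  n_tip <- n0
  next_node <- n_tip + 1L
  active <- seq_len(n0)              # node ids of active clusters
  # representative label per active cluster for deterministic tie-breaks:
  # the lexicographically smallest tip label below the cluster
  rep_lab <- labels
  D <- d
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0)
  while (length(active) > 3L) {
    n <- length(active)
    S <- rowSums(D)
    Q <- (n - 2) * D - outer(S, S, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # lexicographic tie-break on sorted label pairs
    keys <- apply(cand, 1L, function(ij) {
      p <- sort(c(rep_lab[ij[1L]], rep_lab[ij[2L]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    dij <- D[i, j]
    li <- dij / 2 + (S[i] - S[j]) / (2 * (n - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    new_id <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(new_id, active[i]), c(new_id, active[j]))
    lens <- c(lens, li, lj)
    # distances to the new cluster
    rest <- setdiff(seq_len(n), c(i, j))
    newd <- (D[i, rest] + D[j, rest] - dij) / 2
    D2 <- matrix(0, n - 1L, n - 1L)
    D2[1:(n - 2L), 1:(n - 2L)] <- D[rest, rest]
    D2[n - 1L, 1:(n - 2L)] <- newd
    D2[1:(n - 2L), n - 1L] <- newd
    D <- D2
    active <- c(active[rest], new_id)
    rep_lab <- c(rep_lab[rest], min(rep_lab[c(i, j)]))
  }
  # final three clusters joined at the central node (closed form)
  i <- 1L; j <- 2L; k <- 3L
  la <- (D[i, j] + D[i, k] - D[j, k]) / 2
  lb <- (D[i, j] + D[j, k] - D[i, k]) / 2
  lc <- (D[i, k] + D[j, k] - D[i, j]) / 2
  center <- next_node
  edges <- rbind(edges, c(center, active[i]), c(center, active[j]),
                 c(center, active[k]))
  lens <- c(lens, max(la, 0), max(lb, 0), max(lc, 0))
  # renumber internal nodes to ape convention (root = n_tip + 1, preorder)
  n_internal <- next_node - n_tip
  # map: center node becomes n_tip+1; remaining internals numbered by DFS
  new_ids <- integer(next_node)
  new_ids[seq_len(n_tip)] <- seq_len(n_tip)
  counter <- n_tip
  adj <- split(seq_len(nrow(edges)), edges[, 1L])
  assign_ids <- function(node) {
    counter <<- counter + 1L
    new_ids[node] <<- counter
    for (e in adj[[as.character(node)]]) {
      child <- edges[e, 2L]
      if (child > n_tip) assign_ids(child)
    }
  }
  assign_ids(center)
  edge_new <- cbind(new_ids[edges[, 1L]], new_ids[edges[, 2L]])
  # ape expects edges in preorder-ish ordering; build via reorder
  tr <- structure(list(edge = edge_new, edge.length = lens,
                       Nnode = n_internal, tip.label = labels),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Unrooted bipartitions (splits) of a tree
#'
#' Each internal edge is reported as the side of the split not containing
#' the alphabetically first tip label, encoded as a sorted
#' `|`-joined label string. Trivial splits are omitted.
#'
#' @param tree `phylo` object.
#' @return Character vector of canonical split keys.
#' @export
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  n_tip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  keys <- character(0)
  for (p in parts) {
    side <- sort(labs[p])
    if (anchor %in% side) side <- sort(setdiff(tips, side))
    if (length(side) >= 2L && length(side) <= n_tip - 2L)
      keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Columns are resampled with replacement `replicates` times; the support
#' of each internal bipartition of the full-data NJ tree is the percentage
#' of replicate trees containing it. All supports are retained in the
#' returned tree (`node.label`); display layers conventionally hide values
#' below 50.
#'
#' @param alignment `alignment_set` with >= 4 members.
#' @param replicates bootstrap replicates (default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @param model distance model passed to [p_distance()].
#' @return The full-data NJ `phylo` tree with integer percent supports as
#'   `node.label` (root/trivial nodes carry NA) and a `supports` attribute
#'   mapping split keys to percentages.
#' @export
bootstrap_support <- function(alignment, replicates = 1000L, seed = 1L,
                              model = "p") {
  if (length(alignment$members) < 4L)
    stop("bootstrap_support requires >= 4 sequences")
  if (replicates < 1L) stop("replicates must be >= 1")
  m <- .aln_matrix(alignment$members)
  taxa <- names(alignment$members)
  full <- nj_tree(p_distance(alignment, model))
  keys <- tree_splits(full)
  counts <- setNames(numeric(length(keys)), keys)
  L <- ncol(m)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    mb <- m[, cols, drop = FALSE]
    memb <- setNames(apply(mb, 1L, paste, collapse = ""), taxa)
    aln_b <- tryCatch(alignment_set(memb), error = function(e) NULL)
    if (is.null(aln_b)) next
    db <- tryCatch(p_distance(aln_b, model), error = function(e) NULL)
    if (is.null(db)) next
    tb <- nj_tree(db)
    bk <- tree_splits(tb)
    hit <- keys %in% bk
    counts[hit] <- counts[hit] + 1
  }
  supports <- round(100 * counts / replicates)
  # attach node labels: internal node -> its split key (if non-trivial)
  node_lab <- rep(NA_character_, full$Nnode)
  parts <- ape::prop.part(full)
  labs <- attr(parts, "labels")
  tips <- sort(full$tip.label)
  anchor <- tips[1L]
  for (idx in seq_along(parts)) {
    side <- sort(labs[parts[[idx]]])
    if (anchor %in% side) side <- sort(setdiff(tips, side))
    key <- paste(side, collapse = "|")
    if (key %in% names(supports)) node_lab[idx] <- as.character(supports[key])
  }
  full$node.label <- node_lab
  attr(full, "supports") <- supports
  full
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write / read Newick trees
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; branch
#' lengths are serialised to 6 decimals and node labels (bootstrap
#' supports) are preserved.
#'
#' @param tree `phylo` object.
#' @param path file path.
#' @return `write_newick`: the path, invisibly. `read_newick`: a `phylo`.
#' @export
write_newick <- function(tree, path) {
  tree$edge.length <- round(tree$edge.length, 6L)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(txt)) stop("empty Newick file")
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  n_open <- sum(chars == "(")
  n_close <- sum(chars == ")")
  if (n_open != n_close)
    stop(sprintf("malformed Newick: %d '(' vs %d ')'", n_open, n_close))
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("malformed Newick: parser returned no tree")
  tr
}
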