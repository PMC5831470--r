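test_that("p-distance uses pairwise deletion and validates input", {
  aln <- alignment_set(c(a = "AAAA", b = "AATT", c = "AA-A"))
  d <- p_distance(aln)
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 0)      # 3 comparable columns, all equal
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 3L), c("a", "b", "c")))
  bad <- alignment_set(c(a = "A-", b = "-A", c = "AA"))
  expect_error(p_distance(bad), "no comparable columns")
  # poisson correction inflates distances
  aln2 <- alignment_set(c(a = "AAAAAAAA", b = "AATTAAAA", c = "AAAAAATT"))
  expect_true(all(p_distance(aln2, "poisson") >= p_distance(aln2)))
})

test_that("NJ recovers known topologies and resolves ties deterministically", {
  # 3 taxa: closed-form branch lengths
  d3 <- matrix(c(0, 3, 5, 3, 0, 4, 5, 4, 0), 3L, 3L,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  bl <- setNames(t3$edge.length[match(1:3, t3$edge[, 2L])], t3$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(2, 1, 3))
  # 4-taxon additive matrix with split AB|CD
  d4 <- matrix(6, 4L, 4L, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d4[1, 2] <- d4[2, 1] <- 2; d4[3, 4] <- d4[4, 3] <- 2; diag(d4) <- 0
  t4 <- nj_tree(d4)
  expect_equal(tree_splits(t4), "C|D")
  # all-equal off-diagonal: deterministic output under the tie rule
  de <- matrix(1, 5L, 5L, dimnames = list(letters[1:5], letters[1:5]))
  diag(de) <- 0
  expect_equal(ape::write.tree(nj_tree(de)), ape::write.tree(nj_tree(de)))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2L, 2L)), ">= 3 taxa")
  asym <- d4; asym[1, 2] <- 3
  expect_error(nj_tree(asym), "symmetric")
})

test_that("NJ returns the generating tree for random additive matrices", {
  set.seed(123)
  for (i in 1:50) {
    n <- sample(4:8, 1L)
    t0 <- ape::rtree(n)
    t0$edge.length <- runif(nrow(t0$edge), 0.5, 2)
    d0 <- stats::cophenetic(t0)
    d0 <- d0[sample(rownames(d0)), , drop = FALSE][, rownames(d0)]
    d0 <- d0[, rownames(d0)]
    tr <- nj_tree(d0)
    expect_equal(as.numeric(ape::dist.topo(tr, ape::unroot(t0))), 0)
    # path distances reproduce the additive matrix
    dback <- stats::cophenetic(tr)[rownames(d0), colnames(d0)]
    expect_equal(dback, d0, tolerance = 1e-8)
  }
})

test_that("NJ agrees topologically with an independent implementation", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(5:8, 1L)
    d <- as.matrix(stats::dist(matrix(runif(n * 4), n)))
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    expect_equal(as.numeric(ape::dist.topo(nj_tree(d), ape::nj(d))), 0)
  }
})

test_that("bootstrap supports are reproducible, order-invariant and saturate", {
  block <- function(x, k) strrep(x, k)
  memb <- c(A = paste0(block("A", 10L), block("C", 10L)),
            B = paste0(block("A", 10L), block("C", 10L)),
            C = paste0(block("W", 10L), block("C", 10L)),
            D = paste0(block("W", 10L), block("Y", 10L)),
            E = paste0(block("W", 10L), block("Y", 10L)))
  aln <- alignment_set(memb)
  t1 <- bootstrap_support(aln, replicates = 100L, seed = 7L)
  t2 <- bootstrap_support(aln, replicates = 100L, seed = 7L)
  expect_equal(attr(t1, "supports"), attr(t2, "supports"))
  # both true splits ({A,B} and {D,E}) are present in every replicate;
  # keys name the side not containing the first taxon
  expect_equal(unname(attr(t1, "supports")["C|D|E"]), 100)
  expect_equal(unname(attr(t1, "supports")["D|E"]), 100)
  # taxon input order does not change split supports
  aln_perm <- alignment_set(memb[c("D", "B", "E", "A", "C")])
  t3 <- bootstrap_support(aln_perm, replicates = 100L, seed = 7L)
  expect_equal(attr(t3, "supports")[names(attr(t1, "supports"))],
               attr(t1, "supports"))
  expect_error(bootstrap_support(aln, replicates = 0L), "replicates")
})

test_that("bootstrap supports at 100 vs 1000 replicates agree for strong clades", {
  set.seed(17)
  cfg <- synthetic_config(seed = 17L, substitution_rate = 0.05,
                          n_per_family = 2L,
                          species_tree = paste0("(((s1:0.1,s2:0.1):0.1,",
                                                "(s3:0.1,s4:0.1):0.1):0.05,",
                                                "((s5:0.1,s6:0.1):0.1,",
                                                "(s7:0.1,s8:0.1):0.1):0.05);"),
                          n_species = 8L)
  sim <- generate_study(cfg)
  seqs <- vapply(names(sim$species), function(sp)
    paste(vapply(sim$species[[sp]], function(p) p$record$residues, ""),
          collapse = ""), "")
  aln <- alignment_set(seqs)
  s100 <- attr(bootstrap_support(aln, 100L, seed = 5L), "supports")
  s1000 <- attr(bootstrap_support(aln, 1000L, seed = 5L), "supports")
  strong <- names(s1000)[s1000 >= 90]
  expect_gt(length(strong), 0L)
  expect_true(all(abs(s100[strong] - s1000[strong]) <= 5))
})

test_that("Newick round trip preserves topology, lengths and supports", {
  d3 <- matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3L,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(t3, f)
  txt <- readLines(f)
  expect_match(txt, "^\\(.*A:1.*\\);$")
  back <- read_newick(f)
  expect_equal(as.numeric(ape::dist.topo(back, t3)), 0)
  expect_equal(sort(back$edge.length), sort(t3$edge.length), tolerance = 1e-6)
  writeLines("((A:1,B:1,C:1);", f)
  expect_error(read_newick(f), "malformed")
})
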