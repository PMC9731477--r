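test_that("pseudochromosomes apply substitutions and deletions in place", {
  pc <- build_pseudochromosome("ACGTACGT",
                               data.frame(position = c(2, 4),
                                          type = c("substitution", "deletion"),
                                          alt = c("T", "2")))
  expect_identical(pc$seq, "ACTT--GT")
  expect_equal(pc$length, 8)
  # no variants: identity
  none <- build_pseudochromosome("ACGT", data.frame(position = numeric(),
                                                    type = character(),
                                                    alt = character()))
  expect_identical(none$seq, "ACGT")
  # insertions ignored with a counted warning
  expect_warning(
    ins <- build_pseudochromosome("ACGT",
                                  data.frame(position = 1,
                                             type = "insertion", alt = "AA")),
    "1 insertion")
  expect_identical(ins$seq, "ACGT")
  expect_error(build_pseudochromosome("ACGT",
                                      data.frame(position = c(1, 1),
                                                 type = rep("substitution", 2),
                                                 alt = c("C", "G"))),
               "conflicting")
})

test_that("pseudochromosome length is preserved on randomized variant sets", {
  set.seed(55)
  for (rep in 1:20) {
    L <- sample(50:300, 1)
    ref <- random_dna(L)
    n_sub <- sample(0:10, 1)
    pos <- sample(0:(L - 1), n_sub)
    vars <- data.frame(position = pos,
                       type = rep("substitution", n_sub),
                       alt = sample(c("A", "C", "G", "T"), n_sub,
                                    replace = TRUE))
    # a deletion in the untouched tail
    free <- setdiff(0:(L - 6), pos)
    free <- free[!free %in% unlist(lapply(pos, function(p) p))]
    if (length(free)) {
      dstart <- sample(free, 1)
      if (!any(pos > dstart & pos < dstart + 3)) {
        vars <- rbind(vars, data.frame(position = dstart, type = "deletion",
                                       alt = "3"))
      }
    }
    pc <- build_pseudochromosome(ref, vars)
    expect_equal(nchar(pc$seq), L)
  }
})

test_that("pairwise distance uses pairwise deletion of gap columns", {
  expect_equal(pairwise_distance("AAAA", "AAAA")$p_distance, 0)
  expect_equal(pairwise_distance("AAAA", "AAAT")$p_distance, 0.25)
  d <- pairwise_distance("A-AA", "ATAA")
  expect_equal(d$p_distance, 0)
  expect_equal(d$sites_used, 3)
  expect_error(pairwise_distance("--", "AA"), "no comparable")
  expect_error(pairwise_distance("AAA", "AA"), "equal length")
})

test_that("nucleotide diversity equals the brute-force oracle", {
  expect_equal(nucleotide_diversity(list("AAAA", "AAAA"))$pi_mean, 0)
  est <- nucleotide_diversity(list("AAAA", "AAAT", "AATT"))
  expect_equal(est$pi_mean, 1 / 3)
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    L <- sample(40:120, 1)
    seqs <- replicate(n, paste(sample(c("A", "C", "G", "T", "-"), L,
                                      replace = TRUE,
                                      prob = c(rep(0.23, 4), 0.08)),
                               collapse = ""))
    est <- nucleotide_diversity(as.list(seqs))
    oracle <- pi_oracle(as.list(seqs))
    expect_equal(est$pi_mean, unname(oracle["mean"]), tolerance = 1e-12)
    expect_equal(est$pi_sd, unname(oracle["sd"]), tolerance = 1e-12)
    # order invariance
    perm <- sample(n)
    expect_equal(nucleotide_diversity(as.list(seqs[perm]))$pi_mean,
                 est$pi_mean, tolerance = 1e-12)
  }
})

test_that("global identity follows the stated conventions", {
  expect_equal(global_identity("ACGTACGTAC", "ACGTACGTAC"), 100.0)
  expect_equal(global_identity("ACGT", "ACGA"), 75.0)
  # equal-length gapless comparison reduces to Hamming identity
  set.seed(3)
  a <- random_dna(200)
  av <- strsplit(a, "")[[1]]
  idx <- sample(200, 6)
  bv <- av
  for (i in idx) bv[i] <- setdiff(c("A", "C", "G", "T"), av[i])[1]
  expect_equal(global_identity(a, paste(bv, collapse = "")),
               round(100 * (1 - 6 / 200), 1))
})

test_that("neighbor joining recovers additive trees", {
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_tree(d3)
  expect_equal(ape::Ntip(tr3), 3)
  # three-point closed form: branch lengths a=1, b=2, c=3
  el <- stats::setNames(tr3$edge.length,
                        tr3$tip.label[tr3$edge[, 2]])
  expect_equal(unname(el[c("A", "B", "C")]), c(1, 2, 3))
  # additive 4-taxon matrix from ((A,B),(C,D))
  lab <- c("A", "B", "C", "D")
  d4 <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, dimnames = list(lab, lab))
  tr4 <- nj_tree(d4)
  truth <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(ape::dist.topo(ape::unroot(tr4), ape::unroot(truth)), 0,
               ignore_attr = TRUE)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("trees are recovered from simulated population distances", {
  loc <- realize_reference(build_default_layout(), 0.4, seed = 8)
  truth <- ape::read.tree(
    text = "(((t1:1,t2:1):1,(t3:1,t4:1):1):1,t5:3);")
  pop <- simulate_population(loc, 5, tree = truth, mu = 0.01,
                             orientation_flip_prob = 0, seed = 9)
  d <- p_distance_matrix(lapply(pop$strains, `[[`, "seq"))
  nj <- nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(nj), ape::unroot(truth)), 0,
               ignore_attr = TRUE)
})

test_that("Fitch counts match spec cases and are invariant to rerooting", {
  tr <- "((A,B),(C,D));"
  expect_equal(fitch_min_changes(tr, c(A = "REF", B = "REF", C = "REF",
                                       D = "REF")), 0)
  expect_equal(fitch_min_changes(tr, c(A = "REF", B = "INV", C = "REF",
                                       D = "INV")), 2)
  tree <- ape::read.tree(text = "(((A,B),C),(D,(E,F)));")
  states <- c(A = "INV", B = "REF", C = "INV", D = "REF", E = "REF",
              F = "INV")
  base <- fitch_min_changes(tree, states)
  expect_equal(base, fitch_oracle(tree, states))
  for (node in (ape::Ntip(tree) + 2):(ape::Ntip(tree) + tree$Nnode)) {
    rerooted <- ape::root(tree, node = node, resolve.root = TRUE)
    expect_equal(fitch_min_changes(rerooted, states), base)
  }
})

test_that("Fitch equals the exhaustive oracle on random trees", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(4:8, 1)
    tree <- ape::rtree(n)
    states <- stats::setNames(sample(c("REF", "INV"), n, replace = TRUE),
                              tree$tip.label)
    expect_equal(fitch_min_changes(tree, states),
                 fitch_oracle(tree, states))
    # independent library cross-check on a subset
    if (rep <= 10 && requireNamespace("phangorn", quietly = TRUE)) {
      pd <- phangorn::phyDat(matrix(states[tree$tip.label], ncol = 1,
                                    dimnames = list(tree$tip.label, NULL)),
                             type = "USER", levels = c("REF", "INV"))
      expect_equal(fitch_min_changes(tree, states),
                   phangorn::fitch(tree, pd))
    }
    # parsimony never exceeds the minority class size
    expect_lte(fitch_min_changes(tree, states),
               min(table(factor(states, c("REF", "INV")))) +
                 (length(unique(states)) == 1))
  }
  expect_error(fitch_min_changes("((A,B),C);", c(A = "REF", B = "INV")),
               "unlabeled")
})

test_that("concerted-evolution index flags mutual nearest neighbors", {
  lab <- c("IRL_s1", "IRR_s1", "IRL_s2", "IRR_s2")
  d <- matrix(c(0, 0.01, 0.30, 0.30,
                0.01, 0, 0.30, 0.30,
                0.30, 0.30, 0, 0.02,
                0.30, 0.30, 0.02, 0), 4, dimnames = list(lab, lab))
  res <- concerted_evolution_index(d, list(c("IRL_s1", "IRR_s1"),
                                           c("IRL_s2", "IRR_s2")))
  expect_equal(res$index, 1)
  # orthologous clustering: copies closest across strains
  d2 <- matrix(c(0, 0.30, 0.01, 0.30,
                 0.30, 0, 0.30, 0.02,
                 0.01, 0.30, 0, 0.30,
                 0.30, 0.02, 0.30, 0), 4, dimnames = list(lab, lab))
  expect_equal(concerted_evolution_index(
    d2, list(c("IRL_s1", "IRR_s1"), c("IRL_s2", "IRR_s2")))$index, 0)
  # conservative tie handling: a tied nearest neighbor is not mutual
  d3 <- matrix(0.1, 4, 4, dimnames = list(lab, lab))
  diag(d3) <- 0
  expect_equal(concerted_evolution_index(
    d3, list(c("IRL_s1", "IRR_s1")))$index, 0)
  expect_error(concerted_evolution_index(d, list(c("IRL_s1", "nope"))),
               "missing")
})
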