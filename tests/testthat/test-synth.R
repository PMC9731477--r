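test_that("population simulation: no mutation and no flips gives clones", {
  loc <- realize_reference(small_layout(), 0.4, seed = 1)
  pop <- simulate_population(loc, 6, mu = 0, orientation_flip_prob = 0,
                             seed = 2)
  expect_true(all(vapply(pop$strains, function(s) s$seq == loc$seq,
                         logical(1))))
  expect_true(all(pop$orientations == "REF"))
  expect_equal(nrow(pop$truth), 0)
})

test_that("population simulation is seed-deterministic", {
  loc <- realize_reference(small_layout(), 0.4, seed = 1)
  a <- simulate_population(loc, 5, mu = 0.01, orientation_flip_prob = 0.2,
                           seed = 42)
  b <- simulate_population(loc, 5, mu = 0.01, orientation_flip_prob = 0.2,
                           seed = 42)
  expect_identical(lapply(a$strains, `[[`, "seq"),
                   lapply(b$strains, `[[`, "seq"))
  expect_identical(a$orientations, b$orientations)
})

test_that("star-tree divergence matches the neutral expectation", {
  loc <- realize_reference(build_default_layout(), 0.4, seed = 3)
  n <- 6
  star <- ape::read.tree(
    text = paste0("(", paste0("t", 1:n, ":1", collapse = ","), ");"))
  mu <- 0.002
  pop <- simulate_population(loc, n, tree = star, mu = mu,
                             orientation_flip_prob = 0, seed = 4)
  L <- nchar(loc$seq)
  d <- p_distance_matrix(lapply(pop$strains, `[[`, "seq"))
  mean_p <- mean(d[upper.tri(d)])
  # each pair separated by 2 branch-length units; back-mutation negligible
  expect_lt(abs(mean_p - 2 * mu) / (2 * mu), 0.2)
})

test_that("recorded flips bound the Fitch parsimony count", {
  loc <- realize_reference(small_layout(), 0.4, seed = 3)
  for (seed in 1:5) {
    pop <- simulate_population(loc, 8, mu = 0,
                               orientation_flip_prob = 0.3, seed = seed)
    if (length(unique(pop$orientations)) < 2) next
    fc <- fitch_min_changes(pop$tree, pop$orientations)
    expect_lte(fc, nrow(pop$truth))
  }
})

test_that("variants recorded for a strain reconstruct its REF-frame sequence", {
  loc <- realize_reference(small_layout(), 0.4, seed = 9)
  pop <- simulate_population(loc, 4, mu = 0.01, orientation_flip_prob = 0,
                             seed = 10)
  s <- pop$strains[[2]]
  pc <- build_pseudochromosome(loc$seq, s$variants, s$strain_id)
  expect_identical(pc$seq, s$seq)
})

test_that("a cross with no crossovers yields purely parental segregants", {
  cfg <- cross_config(co_rate = 0, n_segregants = 20, seed = 1)
  cr <- simulate_cross("REF", "REF", cfg)
  expect_equal(nrow(cr$truth), 0)
  g <- unclass(cr$genotypes)
  expect_true(all(apply(g, 1, function(r) length(unique(r)) == 1)))
})

test_that("mechanistic REF x INV crosses admit only even crossover parity in FF", {
  cfg <- cross_config(n_segregants = 400, seed = 8)
  cr <- simulate_cross("REF", "INV", cfg)
  ff <- cfg$ff_interval
  per_seg <- tapply(cr$truth$position, cr$truth$segregant, function(p) {
    sum(p > ff[1] & p < ff[2])
  })
  expect_true(all(per_seg %% 2 == 0))
  cl <- classify_region_events(call_crossovers(cr$genotypes), ff)
  expect_equal(unname(cl$counts["ff_single"]), 0)
})

test_that("REF x REF crossover density in FF is indistinguishable from flanks", {
  cfg <- cross_config(n_segregants = 400, seed = 9)
  cr <- simulate_cross("REF", "REF", cfg)
  ff <- cfg$ff_interval
  n_ff <- sum(cr$truth$position > ff[1] & cr$truth$position < ff[2])
  bt <- stats::binom.test(n_ff, nrow(cr$truth),
                          p = diff(ff) / cfg$chrom_length)
  expect_gt(bt$p.value, 0.01)
})

test_that("four-parent intercross with zero generations returns founders", {
  fp <- simulate_four_parent_intercross(generations = 0, n_final = 30,
                                        config = cross_config(seed = 3))
  g <- unclass(fp$genotypes)
  # each segregant is a single founder haplotype: its non-NA cells are all
  # one letter and cover exactly that parent's sites
  for (i in seq_len(nrow(g))) {
    seen <- unique(stats::na.omit(g[i, ]))
    expect_length(seen, 1)
  }
})

test_that("four-parent intercross: INV parent FF sites form one LD block", {
  fp <- simulate_four_parent_intercross(config = cross_config(seed = 5))
  ff <- cross_config()$ff_interval
  inv <- names(fp$orientations)[fp$orientations == "INV"]
  pm <- presence_matrix(fp$genotypes, inv,
                        sites = fp$parent_sites$pos[
                          fp$parent_sites$parent == inv],
                        region = ff)
  ld <- complete_ld_pairs(pm)
  expect_equal(length(unique(ld$classes)), 1)
  # and with all-REF founders the same parent's FF sites recombine freely
  fp0 <- simulate_four_parent_intercross(config = cross_config(seed = 5),
                                         inv_parent = 0)
  classes0 <- vapply(LETTERS[1:4], function(p) {
    pm0 <- presence_matrix(fp0$genotypes, p,
                           sites = fp0$parent_sites$pos[
                             fp0$parent_sites$parent == p],
                           region = ff)
    length(unique(complete_ld_pairs(pm0)$classes))
  }, integer(1))
  expect_true(all(classes0 >= 2))
})

test_that("read simulation respects mixture proportions and junctions", {
  loc <- default_locus()
  jr <- junction_references(loc)
  reads_ref <- simulate_reads(loc, 6000, coverage = 20, het_mixture = 0,
                              seed = 2)
  expect_true(all(attr(reads_ref, "truth") == "REF"))
  call <- call_orientation_reads(reads_ref, jr)
  expect_equal(call$state, "REF")
  expect_equal(sum(call$evidence$inv), 0)
  # reads shorter than the IR cannot span it: AMBIGUOUS
  short <- simulate_reads(loc, 2000, coverage = 20, het_mixture = 0.5,
                          seed = 3)
  expect_equal(call_orientation_reads(short, jr)$state, "AMBIGUOUS")
})

test_that("annotation generator places families as requested", {
  ann <- simulate_annotation(n_genes = 100, k = 6,
                             family_placement = "near_cen",
                             near_cen_window = 60000, seed = 1)
  d <- flipflopr:::all_gene_distances(ann)
  expect_true(all(d[ann$family_ids] <= 60000 + 750))  # half gene length slack
  expect_error(simulate_annotation(chromosome_lengths = 50000,
                                   near_cen_window = 60000),
               "window")
  expect_error(simulate_annotation(n_genes = 3, k = 8), "n_genes")
})
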