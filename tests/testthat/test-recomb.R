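toy_matrix <- function(rows, pos = NULL, chrom = "chr1") {
  m <- do.call(rbind, lapply(rows, function(r) r))
  if (is.null(pos)) pos <- seq(10, by = 10, length.out = ncol(m))
  genotype_matrix(m, paste0("seg", seq_along(rows)),
                  data.frame(chrom = chrom, pos = pos))
}

test_that("crossover calling enumerates switches between informative markers", {
  gm <- toy_matrix(list(c("P1", "P1", "P1", "P1")), pos = c(10, 20, 30, 40))
  expect_equal(nrow(call_crossovers(gm)), 0)

  gm2 <- toy_matrix(list(c("P1", "P1", "P2", "P2")), pos = c(10, 20, 30, 40))
  ev <- call_crossovers(gm2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$left, 20)
  expect_equal(ev$right, 30)

  # NA widens the interval
  gm3 <- toy_matrix(list(c("P1", NA, "P2")), pos = c(10, 20, 30))
  ev3 <- call_crossovers(gm3)
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$left, 10)
  expect_equal(ev3$right, 30)

  # fewer than two informative markers: no events plus a warning
  gm4 <- toy_matrix(list(c("P1", NA, NA)), pos = c(10, 20, 30))
  expect_warning(ev4 <- call_crossovers(gm4), "informative")
  expect_equal(nrow(ev4), 0)
})

test_that("crossover recovery on simulated crosses is exact", {
  cfg <- cross_config(co_rate = 1, n_segregants = 60,
                      marker_positions = seq(1000, 799000, by = 2000),
                      seed = 77)
  cr <- simulate_cross("REF", "REF", cfg)
  ev <- call_crossovers(cr$genotypes)
  mk <- cfg$marker_positions
  for (seg in unique(cr$truth$segregant)) {
    pos <- cr$truth$position[cr$truth$segregant == seg]
    # crossovers before the first or after the last marker are invisible;
    # two crossovers in one marker interval cancel
    iv <- findInterval(pos, mk)
    visible <- iv >= 1 & iv < length(mk)
    parity <- table(iv[visible]) %% 2
    called <- ev[ev$segregant == seg, , drop = FALSE]
    expect_equal(nrow(called), sum(parity == 1))
    # every odd-parity interval is spanned by exactly one called event
    for (k in names(parity)[parity == 1]) {
      i <- as.integer(k)
      hits <- called$left <= mk[i] & called$right >= mk[i + 1]
      expect_equal(sum(hits), 1)
    }
  }
})

test_that("double-crossover pairing inside FF follows max_pair_span", {
  ff <- c(100000, 124000)
  ev <- data.frame(
    segregant = c("s1", "s1", "s2"),
    chrom = "chr1",
    left = c(104000, 107000, 110000),
    right = c(106000, 109000, 112000),
    mid = c(105000, 108000, 111000)
  )
  cl <- classify_region_events(ev, ff)
  expect_equal(unname(cl$counts["ff_double_pairs"]), 1)
  expect_equal(unname(cl$counts["ff_single"]), 1)
  # with a tight span the pair dissolves into singles
  cl2 <- classify_region_events(ev, ff, max_pair_span = 1000)
  expect_equal(unname(cl2$counts["ff_double_pairs"]), 0)
  expect_equal(unname(cl2$counts["ff_single"]), 3)
  # region counts sum to the total
  expect_equal(sum(cl$counts[c("ff_single", "ir", "flank")]) +
                 2 * cl$counts[["ff_double_pairs"]],
               cl$counts[["total"]])
  # no FF events
  ev0 <- ev
  ev0$left <- ev0$left + 1e6
  ev0$right <- ev0$right + 1e6
  ev0$mid <- ev0$mid + 1e6
  expect_equal(unname(classify_region_events(ev0, ff)$counts["ff_single"]), 0)
})

test_that("cumulative curve is a monotone step function conserving totals", {
  expect_equal(nrow(cumulative_curve(
    data.frame(segregant = character(), chrom = character(),
               left = numeric(), right = numeric(), mid = numeric()),
    "chr1")), 0)
  cfg <- cross_config(n_segregants = 150, seed = 13)
  cr <- simulate_cross("REF", "INV", cfg)
  ev <- call_crossovers(cr$genotypes)
  curve <- cumulative_curve(ev, "chrXIV")
  expect_equal(max(curve$cumulative), nrow(ev))
  expect_true(all(diff(curve$cumulative) >= 0))
  # suppression: the FF interval contains (almost) no called events, so the
  # curve is flat across it
  ff <- cfg$ff_interval
  inside <- curve$position > ff[1] & curve$position < ff[2]
  expect_lte(sum(inside), 2)
})

test_that("private-allele detection follows the one-vs-three rule", {
  tab <- data.frame(pos = c(100, 200, 300, 400),
                    p1 = c("A", "A", "A", "A"),
                    p2 = c("C", "A", "C", "C"),
                    p3 = c("C", "C", "G", "C"),
                    p4 = c("C", "C", "C", "A"))
  res <- find_private_alleles(tab)
  # site 100: p1 private; site 200: 2+2 not private; site 300: tri-allelic;
  # site 400: two parents share the minority allele -> not private
  expect_equal(res$private$pos, 100)
  expect_equal(res$private$parent, "p1")
  expect_equal(unname(res$diagnostics["n_multiallelic"]), 1)
})

test_that("complete-LD pairs and classes partition identical presence vectors", {
  m <- cbind(s1 = c(1, 0, 1, 1, 0),
             s2 = c(1, 0, 1, 1, 0),
             s3 = c(1, 0, 0, 1, 0),
             s4 = c(1, 0, 1, 1, 0))
  ld <- complete_ld_pairs(m)
  expect_true(any(ld$pairs$site1 == 1 & ld$pairs$site2 == 2))
  expect_false(any(ld$pairs$site1 == 1 & ld$pairs$site2 == 3))
  expect_equal(unname(ld$classes[1]), unname(ld$classes[2]))
  expect_equal(unname(ld$classes[2]), unname(ld$classes[4]))
  expect_false(ld$classes[1] == ld$classes[3])
  # classes form a partition: membership defined for every site
  expect_length(ld$classes, 4)
  # strict NA handling: a site with an NA cannot pair under the default
  m2 <- m
  m2[1, 2] <- NA
  ld2 <- complete_ld_pairs(m2)
  expect_false(any(ld2$pairs$site1 == 1 & ld2$pairs$site2 == 2))
  # relaxed min_shared restores the pair
  ld3 <- complete_ld_pairs(m2, min_shared = 4)
  expect_true(any(ld3$pairs$site1 == 1 & ld3$pairs$site2 == 2))
})
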