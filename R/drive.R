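#' Describe a REF/INV diploid for meiosis simulation
#'
#' A minimal model of a diploid's chromosome XIV analogue: two haplotypes
#' with an FF-region orientation each, an optional spore-autonomous
#' fluorescent marker located between IRR and the centromere, and the
#' coordinates needed for crossover bookkeeping.
#'
#' @param orientation1,orientation2 `"REF"` or `"INV"` for the two haplotypes.
#' @param marker1,marker2 `"GFP"`, `"RFP"` or `"none"`.
#' @param chrom_length Chromosome length in bp.
#' @param ff_interval 0-based half-open `c(start, end)` of the FF region.
#' @param cen_pos Centromere midpoint (bp); must lie right of the FF region.
#' @param ir_length Length of each IR copy flanking the FF region.
#' @return An object of class `diploid_config`.
#' @export
diploid_config <- function(orientation1 = "REF", orientation2 = "INV",
                           marker1 = "GFP", marker2 = "RFP",
                           chrom_length = 8e5,
                           ff_interval = c(370000, 394000),
                           cen_pos = 424200, ir_length = 4200) {
  stopifnot(orientation1 %in% c("REF", "INV"),
            orientation2 %in% c("REF", "INV"),
            marker1 %in% c("GFP", "RFP", "none"),
            marker2 %in% c("GFP", "RFP", "none"))
  if (cen_pos <= ff_interval[2] + ir_length) {
    stop("'cen_pos' must lie to the right of IRR")
  }
  if (cen_pos >= chrom_length || ff_interval[1] <= ir_length) {
    stop("FF interval, IRs and centromere must fit inside the chromosome")
  }
  structure(list(
    orientations = c(orientation1, orientation2),
    markers = c(marker1, marker2),
    chrom_length = chrom_length,
    ff_interval = ff_interval,
    cen_pos = cen_pos,
    ir_intervals = list(
      irl = c(ff_interval[1] - ir_length, ff_interval[1]),
      irr = c(ff_interval[2], ff_interval[2] + ir_length)
    )
  ), class = "diploid_config")
}

#' Classify the recombinant chromatids of a meiosis
#'
#' Joins chromosome segments by coordinate algebra, honouring each
#' haplotype's FF orientation. For homozygous-orientation diploids, or when
#' an even number of crossovers falls strictly inside the FF region, the two
#' recombinant chromatids are balanced reciprocal products with one
#' centromere each. When the haplotypes have opposite orientations and an
#' odd number of crossovers falls strictly inside FF, the products are
#' isochromosomes: one hairpin carrying two copies of the left arm and no
#' centromere (acentric), and one hairpin carrying two copies of the right
#' arm with two centromeres (dicentric). Total DNA content across the two
#' products is conserved in every configuration, and the centromere counts
#' always sum to 2.
#'
#' A crossover falling inside an IR copy is non-allelic homologous
#' recombination between the repeats rather than allelic exchange in FF: the
#' result is flagged `nahr = TRUE` and returned as a balanced inversion
#' outcome (the FF region between the repeats changes orientation in one
#' product), not an isochromosome.
#'
#' With multiple crossovers of odd in-FF parity, consecutive in-FF
#' crossovers pair off as reciprocal interior patches and the unpaired one
#' sets the gross hairpin structure; the reported segment lists describe
#' that gross structure.
#'
#' @param config A [diploid_config()].
#' @param crossover_positions Numeric crossover positions (bp) within the
#'   chromosome.
#' @return List of two `meiosis_product` objects, each with `segments`
#'   (data frame: `hap`, `start`, `end`, `strand`), `centromere_count` and
#'   `viability` (`"viable"`, `"acentric"` or `"dicentric"`); attribute
#'   `nahr` is `TRUE` when a crossover fell inside an IR.
#' @export
classify_meiosis_products <- function(config, crossover_positions) {
  stopifnot(inherits(config, "diploid_config"))
  x <- sort(as.numeric(crossover_positions))
  L <- config$chrom_length
  if (length(x) && (any(x < 0) || any(x > L))) {
    stop("crossover positions must lie within the chromosome")
  }
  ff <- config$ff_interval
  cen <- config$cen_pos
  in_ir <- vapply(x, function(p) {
    any(vapply(config$ir_intervals,
               function(iv) p > iv[1] && p < iv[2], logical(1)))
  }, logical(1))
  nahr <- any(in_ir)
  hetero <- config$orientations[1] != config$orientations[2]
  in_ff <- x > ff[1] & x < ff[2] & !in_ir
  odd_ff <- hetero && (sum(in_ff) %% 2L == 1L)

  seg <- function(hap, start, end, strand) {
    data.frame(hap = hap, start = start, end = end, strand = strand)
  }
  balanced <- function(xs) {
    # reciprocal alternation in allelic coordinates
    bounds <- c(0, xs, L)
    build <- function(first) {
      haps <- rep(c(first, 3L - first), length.out = length(bounds) - 1L)
      do.call(rbind, lapply(seq_along(haps), function(i) {
        seg(haps[i], bounds[i], bounds[i + 1L], "+")
      }))
    }
    list(build(1L), build(2L))
  }

  if (!odd_ff) {
    parts <- balanced(x)
    products <- lapply(parts, function(p) {
      cen_count <- sum(p$start <= cen & cen < p$end)
      structure(list(segments = p, centromere_count = cen_count,
                     viability = if (cen_count == 1L) "viable"
                                 else if (cen_count == 0L) "acentric"
                                 else "dicentric"),
                class = "meiosis_product")
    })
    if (nahr && hetero) attr(products, "inverted_ff") <- TRUE
    attr(products, "nahr") <- nahr
    return(products)
  }

  # odd number of crossovers strictly inside FF between opposite orientations:
  # the unpaired exchange joins the two left arms (acentric hairpin) and the
  # two right arms (dicentric hairpin)
  ffx <- x[in_ff]
  unpaired <- ffx[length(ffx)]
  inv_hap <- which(config$orientations == "INV")[1]
  mirror <- ff[1] + ff[2] - unpaired
  # physical break position on each haplotype
  brk <- c(unpaired, unpaired)
  brk[inv_hap] <- mirror
  acentric <- rbind(
    seg(1L, 0, brk[1], "+"),
    seg(2L, 0, brk[2], "-")
  )
  dicentric <- rbind(
    seg(1L, brk[1], L, "-"),
    seg(2L, brk[2], L, "+")
  )
  products <- list(
    structure(list(segments = acentric, centromere_count = 0L,
                   viability = "acentric"), class = "meiosis_product"),
    structure(list(segments = dicentric, centromere_count = 2L,
                   viability = "dicentric"), class = "meiosis_product")
  )
  attr(products, "nahr") <- FALSE
  products
}

#' @export
print.meiosis_product <- function(x, ...) {
  cat(sprintf("Meiosis product: %s (%d centromere%s), %d segment(s), %s bp\n",
              x$viability, x$centromere_count,
              if (x$centromere_count == 1L) "" else "s",
              nrow(x$segments),
              format(sum(x$segments$end - x$segments$start),
                     big.mark = ",")))
  invisible(x)
}

#' Simulate single-spore marker counts from a cross
#'
#' Simulates meioses of a marked diploid, applies the
#' isochromosome-viability filter to each sampled gamete chromatid, and
#' counts viable spores expressing each fluorescent marker. Drive is
#' modelled as a gametic transmission-probability shift: the haplotype-1
#' marker is transmitted with probability `0.5 + drive_coeff`. A
#' spore-killing mode (`mode = "spore_killing"`) instead kills spores
#' carrying the haplotype-2 marker with probability `2 * drive_coeff`; both
#' mechanisms reduce to a binomial at the count level.
#'
#' Because the markers sit between IRR and the centromere, the viability
#' filter removes acentric/dicentric chromatids irrespective of which marker
#' they carry, so the viable-spore marker ratio is unbiased when
#' `drive_coeff = 0`.
#'
#' @param config A [diploid_config()].
#' @param n_spores Number of viable spores to score (default 50000).
#' @param drive_coeff Drive coefficient `d`, `|d| <= 0.5`.
#' @param co_rate Expected crossovers per chromatid per meiosis.
#' @param seed Integer seed.
#' @param mode `"transmission"` (default) or `"spore_killing"`.
#' @return List with `counts` (named: `GFP`, `RFP`, `other`), `n_attempted`
#'   meioses and the realized `viable_fraction`.
#' @export
simulate_spores <- function(config, n_spores = 50000, drive_coeff = 0,
                            co_rate = 1.5, seed = 1L,
                            mode = c("transmission", "spore_killing")) {
  stopifnot(inherits(config, "diploid_config"))
  mode <- match.arg(mode)
  if (abs(drive_coeff) > 0.5) stop("|drive_coeff| must be <= 0.5")
  if (n_spores <= 0) {
    return(list(counts = c(GFP = 0L, RFP = 0L, other = 0L),
                n_attempted = 0L, viable_fraction = NA_real_))
  }
  set.seed(as.integer(seed))
  ff <- config$ff_interval
  p_ff <- (ff[2] - ff[1]) / config$chrom_length
  hetero <- config$orientations[1] != config$orientations[2]

  counts <- c(GFP = 0L, RFP = 0L, other = 0L)
  attempted <- 0L
  viable_total <- 0L
  remaining <- n_spores
  while (remaining > 0L) {
    batch <- max(1000L, ceiling(remaining * 1.2))
    k <- stats::rpois(batch, co_rate)
    in_ff <- stats::rbinom(batch, k, p_ff)
    viable <- if (hetero) in_ff %% 2L == 0L else rep(TRUE, batch)
    nv <- sum(viable)
    attempted <- attempted + batch
    viable_total <- viable_total + nv
    nv <- min(nv, remaining)
    if (nv == 0L) next
    if (mode == "transmission") {
      hap1 <- stats::rbinom(nv, 1L, 0.5 + drive_coeff) == 1L
    } else {
      hap1 <- stats::rbinom(nv, 1L, 0.5) == 1L
      killed <- !hap1 & stats::rbinom(nv, 1L, min(1, 2 * abs(drive_coeff))) == 1L
      hap1 <- hap1[!killed]
      nv <- length(hap1)
    }
    m <- ifelse(hap1, config$markers[1], config$markers[2])
    counts["GFP"] <- counts["GFP"] + sum(m == "GFP")
    counts["RFP"] <- counts["RFP"] + sum(m == "RFP")
    counts["other"] <- counts["other"] + sum(m == "none")
    remaining <- n_spores - sum(counts)
  }
  list(counts = counts, n_attempted = attempted,
       viable_fraction = viable_total / attempted)
}

#' Test spore-marker counts for deviation from Mendelian 50:50 transmission
#'
#' Two-sided test of the null hypothesis that the GFP haplotype is
#' transmitted with probability 0.5: an exact binomial test for totals up to
#' 10,000 spores, and the normal approximation with continuity correction
#' above that. A Wilson score confidence interval for the GFP fraction is
#' reported either way.
#'
#' @param gfp_count,rfp_count Spore counts for the two markers.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `drive_test` with `estimate` (GFP fraction),
#'   `p_value`, `conf_int` (Wilson, level `1 - alpha`), `reject`, `n` and
#'   `method`.
#' @export
drive_test <- function(gfp_count, rfp_count, alpha = 0.05) {
  n <- gfp_count + rfp_count
  if (n <= 0) stop("total spore count must be positive")
  if (n <= 10000) {
    ht <- stats::binom.test(gfp_count, n, p = 0.5)
    method <- "exact binomial"
  } else {
    ht <- stats::prop.test(gfp_count, n, p = 0.5, correct = TRUE)
    method <- "normal approximation with continuity correction"
  }
  p_hat <- gfp_count / n
  z <- stats::qnorm(1 - alpha / 2)
  centre <- (p_hat + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  structure(list(
    estimate = p_hat,
    p_value = ht$p.value,
    conf_int = c(centre - half, centre + half),
    reject = ht$p.value < alpha,
    alpha = alpha,
    n = n,
    method = method
  ), class = "drive_test")
}

#' @export
print.drive_test <- function(x, ...) {
  cat("Spore-marker transmission test (H0: p = 0.5)\n")
  cat(sprintf("  n = %s spores, GFP fraction = %.4f (%s)\n",
              format(x$n, big.mark = ","), x$estimate, x$method))
  cat(sprintf("  two-sided p = %.4g; %d%% Wilson CI [%.4f, %.4f]; %s\n",
              x$p_value, round(100 * (1 - x$alpha)), x$conf_int[1],
              x$conf_int[2],
              if (x$reject) "reject Mendelian transmission"
              else "no evidence of drive"))
  invisible(x)
}
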