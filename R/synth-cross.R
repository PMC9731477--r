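#' Configuration for a simulated biparental cross
#'
#' Collects the parameters of a chromosome-scale meiosis model: crossovers
#' along each gamete chromatid follow a stationary gamma renewal process
#' with mean rate `co_rate` per chromosome and interference shape
#' `interference_shape` (shape 1 recovers an interference-free Poisson
#' process; larger shapes suppress closely spaced double crossovers, as
#' yeast meiosis does). In mechanistic mode the isochromosome-viability
#' filter of [classify_meiosis_products()] is applied: gametes whose
#' chromatid carries zero or two centromeres are discarded and resampled,
#' which is what suppresses single crossovers inside FF in REF x INV
#' crosses.
#'
#' @param co_rate Expected crossovers per chromatid per meiosis (default 1.5,
#'   a chromosome XIV-scale genetic length).
#' @param interference_shape Gamma shape of the inter-crossover distance
#'   distribution (default 5, in the range estimated for yeast meiosis;
#'   1 = no interference).
#' @param n_segregants Number of viable segregants to emit.
#' @param suppression_mode `"mechanistic"` or `"off"`.
#' @param marker_positions Strictly increasing marker positions (bp);
#'   default one informative SNP marker every 2 kb, the resolution scale of
#'   the sequenced segregant panels this generator emulates.
#' @param chrom_length Chromosome length in bp (default 800 kb).
#' @param ff_interval 0-based half-open FF interval; defaults place a 24-kb
#'   FF region at 370-394 kb with the centromere 30 kb to its right.
#' @param cen_pos Centromere midpoint.
#' @param ir_length IR copy length (crossovers landing inside an IR are
#'   treated as NAHR, not counted as FF-internal allelic exchange).
#' @param seed Integer seed.
#' @return An object of class `cross_config`.
#' @export
cross_config <- function(co_rate = 1.5, n_segregants = 200,
                         suppression_mode = c("mechanistic", "off"),
                         marker_positions = seq(1000, 799000, by = 2000),
                         chrom_length = 8e5,
                         ff_interval = c(370000, 394000),
                         cen_pos = 424200, ir_length = 4200,
                         interference_shape = 5, seed = 1L) {
  suppression_mode <- match.arg(suppression_mode)
  if (co_rate < 0) stop("'co_rate' must be non-negative")
  if (interference_shape < 1) stop("'interference_shape' must be >= 1")
  if (is.unsorted(marker_positions, strictly = TRUE)) {
    stop("'marker_positions' must be strictly increasing")
  }
  if (length(marker_positions) == 0L) stop("at least one marker is required")
  if (any(marker_positions < 0 | marker_positions > chrom_length)) {
    stop("marker positions must lie within the chromosome")
  }
  structure(list(
    co_rate = co_rate, n_segregants = n_segregants,
    suppression_mode = suppression_mode,
    marker_positions = marker_positions,
    chrom_length = chrom_length, ff_interval = ff_interval,
    cen_pos = cen_pos, ir_length = ir_length,
    interference_shape = interference_shape, seed = as.integer(seed)
  ), class = "cross_config")
}

# crossover positions along one chromatid: stationary gamma renewal process
# with mean inter-crossover distance L / co_rate and the given shape
# (shape 1 = Poisson). A burn-in from well left of the chromosome makes the
# process stationary, so marginal crossover density is uniform.
sample_crossovers <- function(L, co_rate, shape = 1) {
  if (co_rate <= 0) return(numeric())
  if (shape == 1) {
    k <- stats::rpois(1, co_rate)
    return(if (k > 0) sort(stats::runif(k, 0, L)) else numeric())
  }
  mean_gap <- L / co_rate
  pos <- -10 * mean_gap
  out <- numeric()
  repeat {
    pos <- pos + stats::rgamma(1, shape, rate = shape / mean_gap)
    if (pos > L) break
    if (pos >= 0) out <- c(out, pos)
  }
  out
}

# sample one viable gamete chromatid; returns crossover positions
sample_viable_gamete <- function(config, hetero, max_tries = 10000L) {
  dip <- diploid_config(
    orientation1 = "REF", orientation2 = if (hetero) "INV" else "REF",
    chrom_length = config$chrom_length, ff_interval = config$ff_interval,
    cen_pos = config$cen_pos, ir_length = config$ir_length)
  for (try in seq_len(max_tries)) {
    pos <- sample_crossovers(config$chrom_length, config$co_rate,
                             config$interference_shape)
    if (config$suppression_mode == "off" || !hetero || length(pos) == 0L) {
      return(pos)
    }
    prods <- classify_meiosis_products(dip, pos)
    # the sampled chromatid is one of the two recombinant products
    chromatid <- prods[[sample.int(2L, 1L)]]
    if (chromatid$centromere_count == 1L) return(pos)
  }
  stop("failed to sample a viable gamete after ", max_tries,
       " attempts; check 'co_rate'")
}

#' Simulate a biparental cross
#'
#' Simulates `n_segregants` viable random-spore segregants from a cross
#' between two parents, coding each marker by parental origin. Each gamete
#' draws its own Poisson crossover count and uniform positions (a two-strand
#' per-gamete meiosis model); with `suppression_mode = "mechanistic"` and
#' parents of opposite FF orientation, chromatids classified acentric or
#' dicentric by [classify_meiosis_products()] are discarded and resampled,
#' so crossover suppression inside FF emerges from product inviability
#' rather than from an imposed rule.
#'
#' @param parent1,parent2 `strain_record` objects, or orientation strings
#'   (`"REF"`/`"INV"`) for a purely marker-level simulation.
#' @param config A [cross_config()].
#' @return List with `genotypes` (a `genotype_matrix`: segregants x markers,
#'   values `"P1"`/`"P2"`), and `truth` (data frame of true crossover
#'   positions per segregant).
#' @export
simulate_cross <- function(parent1, parent2, config) {
  stopifnot(inherits(config, "cross_config"))
  o1 <- if (inherits(parent1, "strain_record")) parent1$orientation else parent1
  o2 <- if (inherits(parent2, "strain_record")) parent2$orientation else parent2
  stopifnot(o1 %in% c("REF", "INV"), o2 %in% c("REF", "INV"))
  hetero <- o1 != o2
  set.seed(config$seed)
  mk <- config$marker_positions
  n <- config$n_segregants
  geno <- matrix(NA_character_, nrow = n, ncol = length(mk))
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- sample_viable_gamete(config, hetero)
    start_hap <- sample.int(2L, 1L)
    n_below <- findInterval(mk, sort(pos))
    hap <- ifelse((n_below + start_hap) %% 2L == 0L, 2L, 1L)
    geno[i, ] <- paste0("P", hap)
    truth[[i]] <- if (length(pos)) {
      data.frame(segregant = paste0("seg", i), position = sort(pos))
    } else NULL
  }
  gm <- genotype_matrix(
    geno,
    segregant_ids = paste0("seg", seq_len(n)),
    markers = data.frame(chrom = "chrXIV", pos = mk)
  )
  list(genotypes = gm,
       truth = if (any(!vapply(truth, is.null, logical(1)))) {
         do.call(rbind, truth)
       } else data.frame(segregant = character(), position = numeric()))
}

#' Construct a segregant genotype matrix
#'
#' @param x Character matrix, segregants x markers; cells in
#'   `{"P1","P2",NA}` (biparental) or `{"A","B","C","D",NA}` (four-parent
#'   private-allele coding).
#' @param segregant_ids Row names.
#' @param markers Data frame with `chrom` and `pos`; positions must be
#'   strictly increasing within each chromosome.
#' @return A `genotype_matrix`: the matrix with a `markers` attribute.
#' @export
genotype_matrix <- function(x, segregant_ids, markers) {
  stopifnot(is.matrix(x), ncol(x) == nrow(markers),
            all(c("chrom", "pos") %in% names(markers)))
  for (ch in unique(markers$chrom)) {
    if (is.unsorted(markers$pos[markers$chrom == ch], strictly = TRUE)) {
      stop("marker positions must be strictly increasing within chromosome ",
           ch)
    }
  }
  rownames(x) <- segregant_ids
  colnames(x) <- paste0(markers$chrom, ":", markers$pos)
  structure(x, markers = markers, class = c("genotype_matrix", class(x)))
}

#' Read or write a genotype matrix as TSV
#'
#' Rows are segregants, columns are `chrom:pos` markers, cells are parental
#' origin codes or `NA`.
#'
#' @param gm A `genotype_matrix` (for writing).
#' @param path File path.
#' @return `write_genotypes` invisibly returns `path`; `read_genotypes`
#'   returns a `genotype_matrix`.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  utils::write.table(as.data.frame(unclass(gm)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mk <- do.call(rbind, strsplit(colnames(df), ":", fixed = TRUE))
  genotype_matrix(as.matrix(df), rownames(df),
                  data.frame(chrom = mk[, 1], pos = as.numeric(mk[, 2])))
}

#' Simulate a four-parent intercross
#'
#' Emulates a multi-parent advanced intercross: four founder haplotypes, one
#' of them (by default) carrying the INV orientation, undergo `generations`
#' rounds of random mating and meiosis in a finite diploid population, with
#' the same mechanistic viability filter as [simulate_cross()] applied to
#' every gamete of an orientation-heterozygous diploid. Haplotypes are
#' tracked as blocks of parental origin over the private-SNP marker
#' positions, not as full sequences.
#'
#' Each parent contributes `n_private` private SNP sites (positions uniform
#' on the chromosome, plus a guaranteed complement inside the FF region so
#' the FF linkage pattern is observable). The output genotype matrix codes a
#' marker by its owner's letter when the segregant carries the private
#' allele, and `NA` otherwise (the shared allele does not identify its
#' source).
#'
#' @param generations Rounds of random mating (default 12).
#' @param n_final Number of segregants genotyped at the end (default 175).
#' @param config A [cross_config()]; `n_segregants` is ignored here.
#' @param inv_parent Index (1-4) of the single INV founder, or `0` for all
#'   REF founders.
#' @param n_private Private sites per parent outside FF (default 40).
#' @param n_private_ff Additional private sites per parent inside FF
#'   (default 8).
#' @param n_pop Diploid population size per generation (default 200).
#' @return List with `genotypes` (a `genotype_matrix` coded `A`-`D`/`NA`),
#'   `parent_sites` (data frame: `parent`, `pos`), `orientations` of the
#'   founders, and `segregant_orientations`.
#' @export
simulate_four_parent_intercross <- function(generations = 12, n_final = 175,
                                            config = cross_config(),
                                            inv_parent = 4,
                                            n_private = 40,
                                            n_private_ff = 8,
                                            n_pop = 200) {
  stopifnot(inherits(config, "cross_config"))
  if (!inv_parent %in% 0:4) stop("'inv_parent' must be 0 (none) or 1-4")
  set.seed(config$seed)
  parents <- LETTERS[1:4]
  orientations <- rep("REF", 4)
  if (inv_parent > 0) orientations[inv_parent] <- "INV"
  ff <- config$ff_interval
  L <- config$chrom_length

  sites <- do.call(rbind, lapply(1:4, function(p) {
    pos_bg <- stats::runif(n_private, 0, L)
    pos_ff <- stats::runif(n_private_ff, ff[1] + 1, ff[2] - 1)
    data.frame(parent = parents[p], pos = c(pos_bg, pos_ff))
  }))
  sites <- sites[order(sites$pos), , drop = FALSE]
  sites$pos <- round(sites$pos)
  sites <- sites[!duplicated(sites$pos), , drop = FALSE]
  mk <- sites$pos

  # haplotype = list(origin = founder index per marker, orientation)
  founder_hap <- function(p) list(origin = rep.int(p, length(mk)),
                                  orientation = orientations[p])
  meiosis <- function(h1, h2) {
    hetero <- h1$orientation != h2$orientation
    pos <- sample_viable_gamete(config, hetero)
    start_hap <- sample.int(2L, 1L)
    n_below <- findInterval(mk, sort(pos))
    use1 <- (n_below + start_hap) %% 2L == 1L
    origin <- ifelse(use1, h1$origin, h2$origin)
    # a viable gamete has even crossover parity inside FF, so both FF
    # boundaries come from the same haplotype; orientation follows it
    at_ff <- sum(pos < ff[1])
    ori <- if ((at_ff + start_hap) %% 2L == 1L) h1$orientation else
      h2$orientation
    list(origin = origin, orientation = ori)
  }

  # F1: diploids from random pairs of distinct founders
  pop <- lapply(seq_len(n_pop), function(i) {
    pr <- sample.int(4L, 2L)
    list(founder_hap(pr[1]), founder_hap(pr[2]))
  })
  for (g in seq_len(generations)) {
    gametes <- lapply(pop, function(d) meiosis(d[[1]], d[[2]]))
    pop <- lapply(seq_len(n_pop), function(i) {
      pr <- sample.int(n_pop, 2L)
      list(gametes[[pr[1]]], gametes[[pr[2]]])
    })
  }
  segregants <- lapply(seq_len(n_final), function(i) {
    d <- pop[[sample.int(n_pop, 1L)]]
    meiosis(d[[1]], d[[2]])
  })
  if (generations == 0L) {
    # no mating yet: segregants are founder haplotypes
    segregants <- lapply(seq_len(n_final), function(i) {
      founder_hap(sample.int(4L, 1L))
    })
  }

  owner <- match(sites$parent, parents)
  geno <- t(vapply(segregants, function(s) {
    ifelse(s$origin == owner, parents[owner], NA_character_)
  }, character(length(mk))))
  gm <- genotype_matrix(geno, paste0("seg", seq_len(n_final)),
                        data.frame(chrom = "chrXIV", pos = mk))
  list(genotypes = gm,
       parent_sites = sites,
       orientations = stats::setNames(orientations, parents),
       segregant_orientations = vapply(segregants, `[[`, "", "orientation"))
}
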