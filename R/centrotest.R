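#' Distance from a gene to its chromosome's centromere
#'
#' Absolute distance between the gene midpoint and the centromere midpoint
#' on the same chromosome (configurable to edge-to-edge).
#'
#' @param gene One-row data frame (or list) with `chrom`, `start`, `end`.
#' @param annotation List with `genes` and `centromeres` data frames (as
#'   produced by [simulate_annotation()] or [read_annotation_beds()]).
#' @param mode `"midpoint"` (default) or `"edge"` (gene edge to centromere
#'   edge; 0 when they overlap).
#' @return Distance in bp.
#' @export
nearest_centromere_distance <- function(gene, annotation,
                                        mode = c("midpoint", "edge")) {
  mode <- match.arg(mode)
  cen <- annotation$centromeres
  hit <- cen[cen$chrom == gene$chrom, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop("chromosome ", gene$chrom, " has no annotated centromere")
  }
  if (mode == "midpoint") {
    gm <- (gene$start + gene$end) / 2
    cm <- (hit$start + hit$end) / 2
    min(abs(gm - cm))
  } else {
    min(pmax(0, pmax(hit$start - gene$end, gene$start - hit$end)))
  }
}

# vector of distances for all genes, in gene-table order
all_gene_distances <- function(annotation, mode = "midpoint") {
  genes <- annotation$genes
  cen <- annotation$centromeres
  cen_mid <- stats::setNames((cen$start + cen$end) / 2, cen$chrom)
  no_cen <- !genes$chrom %in% cen$chrom
  if (any(no_cen)) {
    warning(sum(no_cen), " gene(s) on centromere-less scaffolds excluded")
    genes <- genes[!no_cen, , drop = FALSE]
  }
  if (mode == "midpoint") {
    gm <- (genes$start + genes$end) / 2
    d <- abs(gm - cen_mid[genes$chrom])
  } else {
    cs <- cen$start[match(genes$chrom, cen$chrom)]
    ce <- cen$end[match(genes$chrom, cen$chrom)]
    d <- pmax(0, pmax(cs - genes$end, genes$start - ce))
  }
  stats::setNames(as.numeric(d), genes$id)
}

#' Median nearest-centromere distance of a gene set
#'
#' @param gene_ids Gene identifiers (must all be present in the annotation).
#' @param annotation List with `genes` and `centromeres` data frames.
#' @param mode Distance mode, see [nearest_centromere_distance()].
#' @return Median distance in bp (even set sizes: mean of the central two).
#' @export
median_family_distance <- function(gene_ids, annotation,
                                   mode = c("midpoint", "edge")) {
  mode <- match.arg(mode)
  d <- all_gene_distances(annotation, mode)
  missing <- setdiff(gene_ids, names(d))
  if (length(missing)) {
    stop("gene id(s) not found in annotation: ",
         paste(missing, collapse = ", "))
  }
  stats::median(d[gene_ids])
}

#' Empirical P for centromere proximity of a gene set, by resampling
#'
#' Compares the observed median nearest-centromere distance of a k-gene set
#' with the distribution of medians of `n_sims` random sets of k distinct
#' genes sampled uniformly without replacement from the annotated genes.
#' The empirical P is the fraction of simulations with median strictly
#' smaller than observed, so `p * n_sims` is exactly the integer count of
#' smaller simulations (e.g. 3 of 1,000,000 gives P = 3e-6). The
#' conservative `(count + 1) / (n_sims + 1)` convention is available via
#' `conservative = TRUE`.
#'
#' @param annotation List with `genes` and `centromeres` data frames.
#' @param k Set size.
#' @param observed_median Observed median distance in bp.
#' @param n_sims Number of simulations (default 1,000,000).
#' @param seed Integer seed.
#' @param mode Distance mode, see [nearest_centromere_distance()].
#' @param conservative Use the `(count + 1)/(n + 1)` estimator.
#' @return An object of class `empirical_p`: `observed_median`, `n_sims`,
#'   `count_below`, `p`, `seed`.
#' @export
permutation_p <- function(annotation, k, observed_median, n_sims = 1e6,
                          seed = 1L, mode = "midpoint",
                          conservative = FALSE) {
  stopifnot(n_sims >= 1)
  d <- all_gene_distances(annotation, mode)
  n <- length(d)
  if (k > n) stop("'k' exceeds the number of annotated genes")
  set.seed(as.integer(seed))
  half <- (k + 1) / 2
  lo <- floor(half)
  hi <- ceiling(half)
  count <- 0L
  for (i in seq_len(n_sims)) {
    x <- d[sample.int(n, k)]
    sx <- sort(x, partial = c(lo, hi))
    med <- (sx[lo] + sx[hi]) / 2
    if (med < observed_median) count <- count + 1L
  }
  p <- if (conservative) (count + 1) / (n_sims + 1) else count / n_sims
  structure(list(observed_median = observed_median,
                 n_sims = as.integer(n_sims), count_below = count, p = p,
                 seed = as.integer(seed), conservative = conservative),
            class = "empirical_p")
}

#' @export
print.empirical_p <- function(x, ...) {
  cat("Centromere-proximity resampling test\n")
  cat(sprintf("  observed median distance: %s bp\n",
              format(x$observed_median, big.mark = ",")))
  cat(sprintf("  %s of %s simulated medians were smaller; P = %.3g%s\n",
              format(x$count_below, big.mark = ","),
              format(x$n_sims, big.mark = ","), x$p,
              if (x$conservative) " (conservative estimator)" else ""))
  invisible(x)
}

#' Exact permutation P by exhaustive enumeration
#'
#' Enumerates every k-subset of the annotated genes and reports the exact
#' fraction with median distance strictly below the observed value. Used as
#' the oracle for [permutation_p()] on small instances.
#'
#' @inheritParams permutation_p
#' @param budget Maximum number of subsets to enumerate (default 2e5).
#' @return List with `p`, `count_below` and `n_subsets`.
#' @export
exhaustive_p <- function(annotation, k, observed_median, mode = "midpoint",
                         budget = 2e5) {
  d <- all_gene_distances(annotation, mode)
  n <- length(d)
  if (k > n) stop("'k' exceeds the number of annotated genes")
  n_subsets <- choose(n, k)
  if (n_subsets > budget) {
    stop("C(", n, ",", k, ") = ", format(n_subsets, big.mark = ","),
         " subsets exceed the enumeration budget; use permutation_p()")
  }
  meds <- utils::combn(d, k, stats::median)
  list(p = sum(meds < observed_median) / n_subsets,
       count_below = sum(meds < observed_median),
       n_subsets = n_subsets)
}

#' Read gene and centromere BED files into an annotation
#'
#' Accepts plain BED (0-based half-open, at least chrom/start/end, name in
#' column 4).
#'
#' @param genes_path,centromeres_path BED file paths.
#' @return List with `genes` (id, chrom, start, end) and `centromeres`
#'   (chrom, start, end).
#' @export
read_annotation_beds <- function(genes_path, centromeres_path) {
  rd <- function(p) utils::read.table(p, sep = "\t", header = FALSE,
                                      stringsAsFactors = FALSE)
  g <- rd(genes_path)
  cen <- rd(centromeres_path)
  list(
    genes = data.frame(id = if (ncol(g) >= 4) g[[4]] else
      paste0("g", seq_len(nrow(g))),
      chrom = g[[1]], start = g[[2]], end = g[[3]]),
    centromeres = data.frame(chrom = cen[[1]], start = cen[[2]],
                             end = cen[[3]])
  )
}
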