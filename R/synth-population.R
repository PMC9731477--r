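#' Simulate a strain population along a phylogeny
#'
#' Evolves a realized locus along a tree: nucleotide substitutions accrue on
#' each branch as a Poisson process (Jukes-Cantor style: a hit site changes
#' to one of the three other bases uniformly), and FF-region orientation
#' evolves as a binary character that flips with a fixed probability per
#' branch. Every flip event is recorded in a truth table, so parsimony
#' estimates of the flip count can be compared with the true history.
#'
#' @param ref A `locus_sequence` in REF orientation (see
#'   [realize_reference()]).
#' @param n_strains Number of strains (tree tips).
#' @param tree Optional `ape::phylo` tree with `n_strains` tips; by default a
#'   random coalescent tree scaled to unit height is drawn.
#' @param mu Substitutions per site per unit branch length.
#' @param orientation_flip_prob Per-branch probability that the FF region
#'   changes orientation.
#' @param seed Integer seed.
#' @return List with `strains` (list of `strain_record`: `strain_id`,
#'   `variants` data frame (`position` 0-based, `type`, `alt`), `orientation`,
#'   `seq`, `irl_seq`, `irr_seq`), `tree`, and `truth` (data frame of flip
#'   events: `edge`, `parent`, `child`) plus a per-tip truth table
#'   `orientations`.
#' @export
simulate_population <- function(ref, n_strains, tree = NULL, mu = 0.004,
                                orientation_flip_prob = 0.1, seed = 1L) {
  stopifnot(inherits(ref, "locus_sequence"), ref$orientation == "REF")
  if (mu < 0) stop("'mu' must be non-negative")
  set.seed(as.integer(seed))
  if (is.null(tree)) {
    tree <- ape::rcoal(n_strains)
    tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  }
  if (length(tree$tip.label) != n_strains) {
    stop("tree has ", length(tree$tip.label), " tips but 'n_strains' is ",
         n_strains)
  }

  L <- nchar(ref$seq)
  root_seq <- strsplit(ref$seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  n_nodes <- max(tree$edge)
  root <- n_strains + 1L
  seqs <- vector("list", n_nodes)
  orients <- character(n_nodes)
  seqs[[root]] <- root_seq
  orients[root] <- "REF"

  flips <- list()
  # cladewise edge order visits every parent before its children
  tree <- stats::reorder(tree, "cladewise")
  for (i in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[i, 1]
    child <- tree$edge[i, 2]
    s <- seqs[[parent]]
    t_len <- tree$edge.length[i]
    n_mut <- stats::rpois(1, mu * t_len * L)
    if (n_mut > 0) {
      pos <- sample.int(L, n_mut, replace = TRUE)
      for (p in pos) {
        s[p] <- sample(setdiff(bases, s[p]), 1)
      }
    }
    seqs[[child]] <- s
    o <- orients[parent]
    if (stats::runif(1) < orientation_flip_prob) {
      o <- if (o == "REF") "INV" else "REF"
      flips[[length(flips) + 1L]] <- data.frame(
        edge = i, parent = parent, child = child)
    }
    orients[child] <- o
  }

  irl <- ref$layout$intervals$irl
  irr <- ref$layout$intervals$irr
  ff <- ref$layout$intervals$ff
  strains <- lapply(seq_len(n_strains), function(i) {
    s <- seqs[[i]]
    diff_pos <- which(s != root_seq)
    variants <- data.frame(
      position = diff_pos - 1L,
      type = rep("substitution", length(diff_pos)),
      alt = s[diff_pos]
    )
    seq_chr <- paste(s, collapse = "")
    if (orients[i] == "INV") {
      ff_seq <- substr(seq_chr, ff[1] + 1L, ff[2])
      substr(seq_chr, ff[1] + 1L, ff[2]) <- revcomp(ff_seq)
    }
    structure(list(
      strain_id = tree$tip.label[i],
      variants = variants,
      orientation = orients[i],
      seq = seq_chr,
      irl_seq = substr(seq_chr, irl[1] + 1L, irl[2]),
      irr_seq = substr(seq_chr, irr[1] + 1L, irr[2])
    ), class = "strain_record")
  })
  names(strains) <- tree$tip.label

  list(
    strains = strains,
    tree = tree,
    truth = if (length(flips)) do.call(rbind, flips)
            else data.frame(edge = integer(), parent = integer(),
                            child = integer()),
    orientations = stats::setNames(orients[seq_len(n_strains)],
                                   tree$tip.label)
  )
}

#' @export
print.strain_record <- function(x, ...) {
  cat(sprintf("Strain %s: %s orientation, %d variant(s)\n",
              x$strain_id, x$orientation, nrow(x$variants)))
  invisible(x)
}

#' Simulate error-free sequencing reads from one or two haplotypes
#'
#' Draws uniform-start reads from a REF haplotype and (for heterozygote
#' emulation) an INV haplotype of the same locus, in proportion
#' `1 - het_mixture` : `het_mixture`. Reads are drawn from either strand.
#' Base-calling errors can be added at a fixed per-base rate; the default is
#' error-free, since orientation calling is junction-topological rather than
#' base-accuracy-sensitive.
#'
#' @param assembly A `locus_sequence` (the REF haplotype; its INV counterpart
#'   is derived with [apply_orientation()] when `het_mixture > 0`).
#' @param read_length Read length in bp; must be shorter than the locus.
#' @param coverage Mean fold coverage.
#' @param het_mixture Proportion of reads drawn from the INV haplotype,
#'   in `[0, 1]`.
#' @param seed Integer seed.
#' @param error_rate Per-base substitution error rate (default 0).
#' @return Character vector of read sequences, named `read1`, `read2`, ...;
#'   attribute `truth` records the source haplotype of each read.
#' @export
simulate_reads <- function(assembly, read_length, coverage = 30,
                           het_mixture = 0, seed = 1L, error_rate = 0) {
  stopifnot(inherits(assembly, "locus_sequence"))
  L <- nchar(assembly$seq)
  if (read_length >= L) stop("'read_length' must be shorter than the locus")
  if (het_mixture < 0 || het_mixture > 1) {
    stop("'het_mixture' must be in [0, 1]")
  }
  set.seed(as.integer(seed))
  n_reads <- max(1L, round(coverage * L / read_length))
  hap_inv <- stats::rbinom(n_reads, 1L, het_mixture) == 1L
  seq_ref <- assembly$seq
  seq_inv <- if (any(hap_inv)) {
    apply_orientation(assembly,
                      if (assembly$orientation == "REF") "INV" else "REF")$seq
  } else seq_ref
  starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
  minus <- stats::rbinom(n_reads, 1L, 0.5) == 1L
  reads <- character(n_reads)
  for (i in seq_len(n_reads)) {
    src <- if (hap_inv[i]) seq_inv else seq_ref
    r <- substr(src, starts[i], starts[i] + read_length - 1L)
    if (error_rate > 0) {
      n_err <- stats::rbinom(1, read_length, error_rate)
      if (n_err > 0) {
        rp <- sample.int(read_length, n_err)
        rv <- strsplit(r, "")[[1]]
        for (p in rp) rv[p] <- sample(setdiff(c("A", "C", "G", "T"), rv[p]), 1)
        r <- paste(rv, collapse = "")
      }
    }
    if (minus[i]) r <- revcomp(r)
    reads[i] <- r
  }
  names(reads) <- paste0("read", seq_len(n_reads))
  attr(reads, "truth") <- ifelse(hap_inv, "INV", assembly$orientation)
  reads
}

#' Simulate a genome annotation with optional centromere-biased gene family
#'
#' Generates a multi-chromosome gene table plus a centromere table, for null
#' calibration and power studies of the centromere-proximity permutation
#' test. Background genes are placed uniformly; the `k` members of a focal
#' gene family are placed either uniformly (`family_placement = "uniform"`,
#' the null) or uniformly within `near_cen_window` bp of a randomly chosen
#' centromere (`"near_cen"`).
#'
#' @param n_chromosomes Number of chromosomes (default 7).
#' @param chromosome_lengths Lengths in bp (recycled; default 1.4 Mb each).
#' @param centromere_positions Optional centromere midpoints per chromosome;
#'   drawn uniformly in the central half of each chromosome when `NULL`.
#' @param n_genes Total number of genes including the family (default 5000).
#' @param k Family size (default 8).
#' @param family_placement `"near_cen"` or `"uniform"`.
#' @param near_cen_window Placement window around the centromere in bp
#'   (default 60000).
#' @param gene_length Gene length in bp (default 1500).
#' @param seed Integer seed.
#' @return List with `genes` (data frame: `id`, `chrom`, `start`, `end`),
#'   `centromeres` (data frame: `chrom`, `start`, `end`) and `family_ids`.
#' @export
simulate_annotation <- function(n_chromosomes = 7,
                                chromosome_lengths = 1.4e6,
                                centromere_positions = NULL,
                                n_genes = 5000, k = 8,
                                family_placement = c("near_cen", "uniform"),
                                near_cen_window = 60000,
                                gene_length = 1500, seed = 1L) {
  family_placement <- match.arg(family_placement)
  set.seed(as.integer(seed))
  lens <- rep_len(chromosome_lengths, n_chromosomes)
  if (near_cen_window >= min(lens)) {
    stop("'near_cen_window' must be smaller than every chromosome")
  }
  if (n_genes < k) stop("'n_genes' must be at least the family size 'k'")
  if (is.null(centromere_positions)) {
    centromere_positions <- round(stats::runif(n_chromosomes,
                                               lens / 4, 3 * lens / 4))
  }
  if (any(centromere_positions <= 0 | centromere_positions >= lens)) {
    stop("centromere positions must lie within their chromosomes")
  }
  chroms <- paste0("chr", seq_len(n_chromosomes))
  cen <- data.frame(chrom = chroms,
                    start = centromere_positions - 60L,
                    end = centromere_positions + 60L)

  n_bg <- n_genes - k
  bg_chrom <- sample.int(n_chromosomes, n_bg, replace = TRUE,
                         prob = lens / sum(lens))
  bg_start <- floor(stats::runif(n_bg, 0, lens[bg_chrom] - gene_length))
  fam_chrom <- sample.int(n_chromosomes, k, replace = TRUE)
  if (family_placement == "near_cen") {
    offset <- stats::runif(k, -near_cen_window, near_cen_window)
    fam_mid <- centromere_positions[fam_chrom] + offset
    fam_mid <- pmin(pmax(fam_mid, gene_length / 2),
                    lens[fam_chrom] - gene_length / 2)
    fam_start <- floor(fam_mid - gene_length / 2)
  } else {
    fam_start <- floor(stats::runif(k, 0, lens[fam_chrom] - gene_length))
  }
  genes <- data.frame(
    id = c(paste0("fam", seq_len(k)), paste0("g", seq_len(n_bg))),
    chrom = chroms[c(fam_chrom, bg_chrom)],
    start = c(fam_start, bg_start),
    end = c(fam_start, bg_start) + gene_length
  )
  list(genes = genes, centromeres = cen,
       family_ids = paste0("fam", seq_len(k)))
}
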