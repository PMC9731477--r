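#' Write per-strain variants onto a reference to build a pseudochromosome
#'
#' Applies substitutions and deletions (but not insertions) to a reference
#' sequence, keeping the output identical in length to the reference:
#' substituted positions carry the alternative base and deleted positions
#' carry `-`. Insertions present in the input are ignored with a counted
#' warning. This length-preserving construction lets per-strain sequences
#' be stacked into an alignment without any multiple-alignment step.
#'
#' @param reference Reference sequence (character scalar).
#' @param variants Data frame with `position` (0-based), `type`
#'   (`"substitution"`, `"deletion"` or `"insertion"`), and `alt`
#'   (alternative base for substitutions, deletion length for deletions).
#' @param strain_id Optional strain identifier carried in the result.
#' @return An object of class `pseudochromosome`: list with `strain_id`,
#'   `seq` (same length as `reference`, over `ACGT-N`) and `length`.
#' @export
build_pseudochromosome <- function(reference, variants,
                                   strain_id = "strain") {
  L <- nchar(reference)
  s <- strsplit(reference, "")[[1]]
  touched <- integer(0)
  n_ins <- 0L
  if (nrow(variants)) {
    for (i in seq_len(nrow(variants))) {
      type <- variants$type[i]
      p0 <- variants$position[i]
      if (type == "insertion") {
        n_ins <- n_ins + 1L
        next
      }
      if (p0 < 0 || p0 >= L) stop("variant position ", p0, " outside reference")
      if (type == "substitution") {
        span <- p0 + 1L
      } else if (type == "deletion") {
        len <- as.integer(variants$alt[i])
        if (p0 + len > L) stop("deletion at ", p0, " runs past the reference")
        span <- (p0 + 1L):(p0 + len)
      } else {
        stop("unknown variant type: ", type)
      }
      if (any(span %in% touched)) {
        stop("conflicting variants at position ",
             span[span %in% touched][1] - 1L)
      }
      touched <- c(touched, span)
      if (type == "substitution") {
        s[span] <- as.character(variants$alt[i])
      } else {
        s[span] <- "-"
      }
    }
  }
  if (n_ins > 0L) {
    warning(n_ins, " insertion(s) ignored (pseudochromosomes are ",
            "length-preserving)")
  }
  structure(list(strain_id = strain_id, seq = paste(s, collapse = ""),
                 length = L),
            class = "pseudochromosome")
}

as_char_vec <- function(x) {
  if (inherits(x, "pseudochromosome")) x <- x$seq
  strsplit(x, "")[[1]]
}

#' Pairwise p-distance with pairwise deletion of gap/ambiguous columns
#'
#' Columns where either sequence carries `-` or `N` are excluded; the
#' distance is the proportion of mismatches among the remaining columns.
#'
#' @param a,b Sequences of equal length (`pseudochromosome` or character).
#' @param region Optional 0-based half-open interval restricting the
#'   comparison.
#' @return List with `p_distance` and `sites_used`. An error is raised when
#'   no comparable sites remain.
#' @export
pairwise_distance <- function(a, b, region = NULL) {
  va <- as_char_vec(a)
  vb <- as_char_vec(b)
  if (length(va) != length(vb)) stop("sequences must have equal length")
  if (!is.null(region)) {
    idx <- (region[1] + 1L):region[2]
    va <- va[idx]
    vb <- vb[idx]
  }
  ok <- !(va %in% c("-", "N")) & !(vb %in% c("-", "N"))
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites between the two sequences")
  list(p_distance = sum(va[ok] != vb[ok]) / n, sites_used = n)
}

#' Nucleotide diversity over a set of aligned sequences
#'
#' Computes the p-distance of every unordered pair (pairwise deletion of
#' gap/`N` columns) and summarizes pi as the mean and sample standard
#' deviation across pairs. A sliding-window mode is available for
#' comparison: with `window` set, pi is computed per window and the s.d. is
#' taken across windows instead.
#'
#' @param seqs List of equal-length sequences (`pseudochromosome` or
#'   character).
#' @param region Optional 0-based half-open interval.
#' @param window,step Optional sliding-window width and step in bp.
#' @return List with `pi_mean`, `pi_sd`, `n_pairs`, `sites_used` (per
#'   pair), and for window mode `windows` (data frame).
#' @export
nucleotide_diversity <- function(seqs, region = NULL, window = NULL,
                                 step = window) {
  if (length(seqs) < 2L) stop("at least two sequences are required")
  if (!is.null(window)) {
    L <- if (is.null(region)) nchar(if (inherits(seqs[[1]],
                                                 "pseudochromosome"))
      seqs[[1]]$seq else seqs[[1]]) else diff(region)
    off <- if (is.null(region)) 0 else region[1]
    starts <- seq(0, L - window, by = step)
    wins <- lapply(starts, function(s) {
      est <- nucleotide_diversity(seqs, region = c(off + s, off + s + window))
      data.frame(start = off + s, end = off + s + window, pi = est$pi_mean)
    })
    wins <- do.call(rbind, wins)
    return(list(pi_mean = mean(wins$pi), pi_sd = stats::sd(wins$pi),
                n_pairs = choose(length(seqs), 2), windows = wins))
  }
  n <- length(seqs)
  ps <- numeric(0)
  used <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- pairwise_distance(seqs[[i]], seqs[[j]], region)
      ps <- c(ps, d$p_distance)
      used <- c(used, d$sites_used)
    }
  }
  list(pi_mean = mean(ps), pi_sd = if (length(ps) > 1L) stats::sd(ps) else 0,
       n_pairs = length(ps), sites_used = used)
}

#' Percent identity from global alignment with free terminal gaps
#'
#' Aligns two sequences globally (match +1, mismatch -1, linear gap -2 by
#' default, terminal gaps free) and reports
#' `100 * matches / aligned columns`, excluding terminal-gap columns from
#' the denominator, rounded to 0.1%. For equal-length gapless homologs this
#' reduces to Hamming identity.
#'
#' @param a,b Sequences (character scalars).
#' @param match,mismatch,gap Alignment scores.
#' @param type Biostrings alignment type (default `"overlap"`, i.e. free
#'   terminal gaps).
#' @return Percent identity (numeric scalar, one decimal).
#' @export
global_identity <- function(a, b, match = 1, mismatch = -1, gap = -2,
                            type = "overlap") {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = -gap,
    type = type)
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  va <- strsplit(pa, "")[[1]]
  vb <- strsplit(pb, "")[[1]]
  matches <- sum(va == vb & va != "-")
  round(100 * matches / length(va), 1)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (via \pkg{ape}) on a validated symmetric
#' distance matrix.
#'
#' @param d Symmetric numeric matrix with zero diagonal and taxon labels,
#'   or a `dist` object.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  if (nrow(d) < 3L) stop("at least three taxa are required")
  ape::nj(stats::as.dist(d))
}

#' Minimum number of binary state changes on a tree (Fitch parsimony)
#'
#' Counts the minimum number of changes of a binary character (e.g. FF
#' orientation REF/INV) needed to explain the tip states on a tree, by the
#' Fitch small-parsimony pass. The count is invariant to the (arbitrary)
#' rooting used internally.
#'
#' @param tree An `ape::phylo` tree or a newick string.
#' @param tip_states Named character vector of states (two levels, e.g.
#'   `"REF"`/`"INV"`) covering every tip.
#' @return Integer minimum change count.
#' @export
fitch_min_changes <- function(tree, tip_states) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  tips <- tree$tip.label
  if (!all(tips %in% names(tip_states))) {
    stop("unlabeled tip(s): ",
         paste(setdiff(tips, names(tip_states)), collapse = ", "))
  }
  states <- unique(tip_states[tips])
  if (length(states) == 1L) return(0L)
  if (length(states) > 2L) stop("only binary characters are supported")
  tree <- ape::multi2di(tree)
  n_tip <- length(tips)
  n_node <- max(tree$edge)
  # state sets as bitmasks: 1, 2, or 3 (= {both})
  mask <- integer(n_node)
  mask[seq_len(n_tip)] <- ifelse(tip_states[tips] == states[1], 1L, 2L)
  changes <- 0L
  edge <- stats::reorder(tree, "postorder")$edge
  kids <- split(edge[, 2], edge[, 1])
  for (node in unique(edge[, 1])) {
    ch <- kids[[as.character(node)]]
    m <- mask[ch[1]]
    for (c2 in ch[-1]) {
      inter <- bitwAnd(m, mask[c2])
      if (inter == 0L) {
        changes <- changes + 1L
        m <- bitwOr(m, mask[c2])
      } else {
        m <- inter
      }
    }
    mask[node] <- m
  }
  changes
}

#' Mutual-nearest-neighbor index of repeat-copy pairs (concerted evolution)
#'
#' For each (IRL, IRR) pair from one strain, flags whether the two copies
#' are each other's nearest neighbors in the distance matrix (excluding
#' self). Under ongoing within-strain homogenization the index approaches
#' 1; without it, copies cluster by locus (orthologs across strains) and
#' the index falls toward the random-pairing expectation. Distance ties are
#' broken conservatively: a tied nearest neighbor does not count as
#' mutual.
#'
#' @param d Symmetric distance matrix with labelled rows/columns.
#' @param pairs List (or 2-column matrix/data frame) of `(IRL_label,
#'   IRR_label)` pairs.
#' @return List with `index` (fraction of mutually-nearest pairs) and
#'   `flags` (logical per pair).
#' @export
concerted_evolution_index <- function(d, pairs) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (is.data.frame(pairs) || is.matrix(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) unlist(pairs[i, ]))
  }
  labs <- rownames(d)
  nearest_is <- function(a, b) {
    others <- setdiff(labs, a)
    dv <- d[a, others]
    best <- min(dv)
    # conservative tie-break: b must be the unique minimum
    sum(dv == best) == 1L && others[which.min(dv)] == b
  }
  flags <- vapply(pairs, function(pr) {
    if (!all(pr %in% labs)) stop("pair member(s) missing from matrix: ",
                                 paste(setdiff(pr, labs), collapse = ", "))
    nearest_is(pr[1], pr[2]) && nearest_is(pr[2], pr[1])
  }, logical(1))
  list(index = mean(flags), flags = flags)
}

#' Distance matrix of p-distances between sequences
#'
#' Convenience wrapper building the matrix consumed by [nj_tree()] and
#' [concerted_evolution_index()].
#'
#' @param seqs Named list or character vector of equal-length sequences.
#' @param region Optional 0-based half-open interval.
#' @return Symmetric numeric matrix of p-distances.
#' @export
p_distance_matrix <- function(seqs, region = NULL) {
  nm <- names(seqs)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- pairwise_distance(seqs[[i]], seqs[[j]],
                                              region)$p_distance
    }
  }
  d
}
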