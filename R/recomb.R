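#' Call crossovers from a segregant genotype matrix
#'
#' For each segregant and chromosome, one crossover event is called per
#' switch of parental origin between consecutive informative (non-`NA`)
#' markers. The event interval is `(left_marker_pos, right_marker_pos]`;
#' uninformative markers between the two widen the interval.
#'
#' @param gm A `genotype_matrix` with biparental coding (`"P1"`/`"P2"`/`NA`).
#' @return Data frame of events: `segregant`, `chrom`, `left`, `right`
#'   (interval bounds in bp), `mid` (interval midpoint). A chromosome with
#'   fewer than two informative markers yields no events, with a warning.
#' @export
call_crossovers <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  markers <- attr(gm, "markers")
  events <- list()
  warned <- character()
  for (ch in unique(markers$chrom)) {
    idx <- which(markers$chrom == ch)
    pos <- markers$pos[idx]
    for (i in seq_len(nrow(gm))) {
      g <- gm[i, idx]
      inf <- which(!is.na(g))
      if (length(inf) < 2L) {
        if (!ch %in% warned) {
          warning("chromosome ", ch, " has fewer than 2 informative markers ",
                  "for at least one segregant; no events called there")
          warned <- c(warned, ch)
        }
        next
      }
      switches <- which(g[inf][-1] != g[inf][-length(inf)])
      for (s in switches) {
        events[[length(events) + 1L]] <- data.frame(
          segregant = rownames(gm)[i], chrom = ch,
          left = pos[inf[s]], right = pos[inf[s + 1L]],
          mid = (pos[inf[s]] + pos[inf[s + 1L]]) / 2
        )
      }
    }
  }
  if (length(events)) do.call(rbind, events)
  else data.frame(segregant = character(), chrom = character(),
                  left = numeric(), right = numeric(), mid = numeric())
}

#' Classify crossover events by region and pair double crossovers
#'
#' Tags each event `FF` when its whole interval lies inside the FF region
#' (the exchange demonstrably occurred there); other events are tagged by
#' their interval midpoint (`IR` or `flank`). Double crossovers are then
#' paired: two consecutive FF events of the same segregant whose midpoints
#' lie within `max_pair_span` bp form one double-crossover pair. In a
#' mechanistic REF x INV cross all FF events should pair up, leaving zero
#' FF singles.
#'
#' @param events Event data frame from [call_crossovers()] (one matrix).
#' @param ff_interval 0-based half-open FF interval.
#' @param max_pair_span Maximum span for pairing (default: the FF length).
#' @param ir_intervals Optional list of IR intervals for the `IR` tag.
#' @return List with `events` (the input plus a `region` tag and `pair_id`),
#'   and `counts`: `ff_single`, `ff_double_pairs`, `ir`, `flank`, `total`.
#' @export
classify_region_events <- function(events, ff_interval,
                                   max_pair_span = diff(ff_interval),
                                   ir_intervals = NULL) {
  region <- rep("flank", nrow(events))
  region[events$left >= ff_interval[1] & events$right <= ff_interval[2]] <- "FF"
  if (!is.null(ir_intervals)) {
    for (iv in ir_intervals) {
      region[events$mid > iv[1] & events$mid < iv[2]] <- "IR"
    }
  }
  events$region <- region
  events$pair_id <- NA_integer_
  pair_n <- 0L
  for (seg in unique(events$segregant[events$region == "FF"])) {
    idx <- which(events$segregant == seg & events$region == "FF")
    idx <- idx[order(events$mid[idx])]
    i <- 1L
    while (i < length(idx)) {
      if (events$mid[idx[i + 1L]] - events$mid[idx[i]] <= max_pair_span) {
        pair_n <- pair_n + 1L
        events$pair_id[idx[c(i, i + 1L)]] <- pair_n
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    }
  }
  ff_idx <- events$region == "FF"
  counts <- c(
    ff_single = sum(ff_idx & is.na(events$pair_id)),
    ff_double_pairs = pair_n,
    ir = sum(events$region == "IR"),
    flank = sum(events$region == "flank"),
    total = nrow(events)
  )
  list(events = events, counts = counts)
}

#' Cumulative crossover curve along a chromosome
#'
#' Step function of the cumulative number of crossover events at event
#' interval midpoints, as used to visualize recombination coldspots: a
#' suppressed region appears as a flat plateau.
#'
#' @param events Event data frame from [call_crossovers()].
#' @param chromosome Chromosome to plot.
#' @return Data frame with `position` (sorted midpoints) and `cumulative`;
#'   zero rows when there are no events.
#' @export
cumulative_curve <- function(events, chromosome) {
  ev <- events[events$chrom == chromosome, , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(data.frame(position = numeric(), cumulative = integer()))
  }
  pos <- sort(ev$mid)
  data.frame(position = pos, cumulative = seq_along(pos))
}

#' Identify SNP alleles private to one of four parents
#'
#' A site is private to parent X when X's allele differs from the allele
#' shared identically by the other three parents. Sites with more than two
#' alleles among the parents are excluded and counted in the diagnostics.
#'
#' @param parent_alleles A data frame or matrix with one row per site and
#'   one column per parent (4 columns) giving the allele observed in each
#'   parent, plus (for data frames) an optional `pos` column of site
#'   positions; rownames or `pos` identify the sites.
#' @return List with `private` (data frame: `pos`, `parent` (column name) )
#'   and `diagnostics` (`n_multiallelic`, `n_uninformative`).
#' @export
find_private_alleles <- function(parent_alleles) {
  df <- as.data.frame(parent_alleles)
  pos <- if ("pos" %in% names(df)) df$pos else seq_len(nrow(df))
  alle <- as.matrix(df[, setdiff(names(df), "pos"), drop = FALSE])
  if (ncol(alle) != 4L) stop("exactly four parents are required")
  parents <- colnames(alle)
  n_multi <- 0L
  n_unif <- 0L
  rows <- list()
  for (i in seq_len(nrow(alle))) {
    a <- alle[i, ]
    tab <- table(a)
    if (length(tab) > 2L) {
      n_multi <- n_multi + 1L
    } else if (length(tab) == 2L && min(tab) == 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        pos = pos[i], parent = parents[which(a == names(tab)[tab == 1L])])
    } else {
      n_unif <- n_unif + 1L
    }
  }
  list(
    private = if (length(rows)) do.call(rbind, rows)
              else data.frame(pos = numeric(), parent = character()),
    diagnostics = c(n_multiallelic = n_multi, n_uninformative = n_unif)
  )
}

#' Find pairs and classes of private sites in complete linkage disequilibrium
#'
#' Two sites are in complete LD when their private-allele presence/absence
#' vectors are identical across segregants. By default identity must hold
#' over every segregant; when `NA` cells are present, two sites are compared
#' only over segregants non-`NA` at both, and a pair is reported only if at
#' least `min_shared` segregants were compared. Complete-LD classes are the
#' transitive closure of the pair relation.
#'
#' @param presence Logical (or 0/1) matrix, segregants x sites; `NA`
#'   allowed.
#' @param min_shared Minimum segregants compared per pair; defaults to all
#'   segregants (strict).
#' @return List with `pairs` (data frame: `site1`, `site2`, columns index
#'   into the site set) and `classes` (integer membership vector, one entry
#'   per site).
#' @export
complete_ld_pairs <- function(presence, min_shared = nrow(presence)) {
  m <- as.matrix(presence)
  storage.mode(m) <- "logical"
  p <- ncol(m)
  parent_of <- seq_len(p)
  find <- function(i) {
    while (parent_of[i] != i) i <- parent_of[i]
    i
  }
  pairs <- list()
  for (i in seq_len(max(p - 1L, 0L))) {
    for (j in (i + 1L):p) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      if (sum(ok) < min_shared) next
      if (all(m[ok, i] == m[ok, j])) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent_of[rj] <- ri
      }
    }
  }
  classes <- vapply(seq_len(p), find, integer(1))
  classes <- match(classes, unique(classes))
  names(classes) <- colnames(m)
  pr <- if (length(pairs)) {
    do.call(rbind, lapply(pairs, function(x) {
      data.frame(site1 = x[1], site2 = x[2])
    }))
  } else data.frame(site1 = integer(), site2 = integer())
  list(pairs = pr, classes = classes)
}

#' Private-allele presence matrix for one parent of a four-parent cross
#'
#' @param gm A four-parent `genotype_matrix` (cells `A`-`D` where the
#'   segregant carries that parent's private allele, `NA` otherwise).
#' @param parent Parent letter.
#' @param sites Optional vector of marker positions owned by the parent
#'   (e.g. from the generator's `parent_sites` truth table); without it,
#'   ownership is inferred from markers where the parent's allele is ever
#'   observed.
#' @param region Optional `c(start, end)` interval restricting the markers.
#' @return Logical matrix segregants x sites: `TRUE` where the segregant
#'   carries the parent's private allele.
#' @export
presence_matrix <- function(gm, parent, sites = NULL, region = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  markers <- attr(gm, "markers")
  keep <- rep(TRUE, ncol(gm))
  if (!is.null(region)) {
    keep <- markers$pos > region[1] & markers$pos < region[2]
  }
  if (!is.null(sites)) {
    keep <- keep & markers$pos %in% sites
  }
  m <- unclass(gm)[, keep, drop = FALSE]
  out <- m == parent
  out[is.na(out)] <- FALSE
  if (is.null(sites)) {
    own <- apply(out, 2, any)
    out <- out[, own, drop = FALSE]
  }
  out
}
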