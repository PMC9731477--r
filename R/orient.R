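#' Build a primer panel for FF-orientation PCR assays
#'
#' Derives four primers from the marker intervals of a REF-orientation
#' locus, mirroring the classic four-reaction assay: pairs 1
#' (outer-left + inner-left) and 2 (inner-right + outer-right) amplify
#' across IRL and IRR only in REF orientation, while pairs 3
#' (outer-left + inner-right) and 4 (inner-left + outer-right) amplify only
#' in INV orientation, because inversion carries the inner markers (the
#' SIW14 / ARK1 proxies) to the opposite ends of the FF region and flips
#' their strands.
#'
#' @param locus A REF-orientation `locus_sequence`.
#' @param primer_length Primer length in nt (default 20; minimum 15).
#' @param max_product Maximum amplicon length in bp (default 10000).
#' @param max_mismatch Mismatches tolerated outside the 3' end (default 0).
#' @return An object of class `primer_panel`: `primers` (named: `outer_left`
#'   forward, `inner_left` reverse, `inner_right` forward, `outer_right`
#'   reverse), `pairs` (list of primer-name pairs for reactions 1-4),
#'   `max_product`, `max_mismatch`.
#' @export
make_primer_panel <- function(locus, primer_length = 20,
                              max_product = 10000, max_mismatch = 0) {
  stopifnot(inherits(locus, "locus_sequence"))
  if (locus$orientation != "REF") {
    stop("the primer panel is defined on a REF-orientation locus")
  }
  if (primer_length < 15) stop("primers must be at least 15 nt")
  iv <- locus$layout$intervals
  take <- function(interval) {
    substr(locus$seq, interval[1] + 1L, interval[1] + primer_length)
  }
  primers <- c(
    outer_left = take(iv$outer_left_marker),           # forward
    inner_left = revcomp(take(iv$inner_left_marker)),  # reverse
    inner_right = take(iv$inner_right_marker),         # forward
    outer_right = revcomp(take(iv$outer_right_marker)) # reverse
  )
  if (anyDuplicated(primers)) stop("panel anchors are not distinct")
  structure(list(
    primers = primers,
    pairs = list(c("outer_left", "inner_left"),
                 c("inner_right", "outer_right"),
                 c("outer_left", "inner_right"),
                 c("inner_left", "outer_right")),
    max_product = max_product,
    max_mismatch = max_mismatch
  ), class = "primer_panel")
}

# primer binding sites on a template; 3' rule: last 3 bases exact,
# remaining positions allow <= max_mismatch mismatches
primer_sites <- function(template, primer, max_mismatch = 0) {
  subj <- Biostrings::DNAString(template)
  hits <- function(p, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(p), subj,
                                  max.mismatch = max_mismatch)
    if (length(m) == 0L) return(NULL)
    df <- data.frame(start = Biostrings::start(m), end = Biostrings::end(m),
                     strand = strand)
    if (max_mismatch > 0) {
      np <- nchar(p)
      keep <- vapply(seq_len(nrow(df)), function(i) {
        site <- substr(template, df$start[i], df$end[i])
        if (strand == "-") site <- revcomp(site)
        substr(site, np - 2L, np) == substr(p, np - 2L, np)
      }, logical(1))
      df <- df[keep, , drop = FALSE]
    }
    df
  }
  rbind(hits(primer, "+"), hits(revcomp(primer), "-"))
}

#' Predict PCR amplicons on a template sequence
#'
#' Reports an amplicon for every pair of primer binding sites on opposite
#' strands with their 3' ends facing each other and separated by at most
#' `max_product` bp. The final 3 bases of each primer must match the
#' template exactly; the remaining positions tolerate up to `max_mismatch`
#' mismatches.
#'
#' @param template Template sequence (character scalar).
#' @param forward_primer,reverse_primer Primer sequences, at least 15 nt.
#' @param max_product Maximum product length in bp.
#' @param max_mismatch Mismatches tolerated outside the 3' end.
#' @return Data frame with one row per amplicon: `start`, `end` (1-based
#'   inclusive template coordinates), `length` and `strand` (strand carrying
#'   the forward primer). Zero rows when there is no product.
#' @export
insilico_pcr <- function(template, forward_primer, reverse_primer,
                         max_product = 10000, max_mismatch = 0) {
  if (nchar(forward_primer) < 15 || nchar(reverse_primer) < 15) {
    stop("primers must be at least 15 nt")
  }
  f <- primer_sites(template, forward_primer, max_mismatch)
  r <- primer_sites(template, reverse_primer, max_mismatch)
  out <- data.frame(start = integer(), end = integer(), length = integer(),
                    strand = character())
  if (is.null(f) || is.null(r) || nrow(f) == 0L || nrow(r) == 0L) return(out)
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(nrow(r))) {
      a <- f[i, ]
      b <- r[j, ]
      if (a$strand == b$strand) next
      plus <- if (a$strand == "+") a else b
      minus <- if (a$strand == "+") b else a
      # 3' of the plus-strand site is its end; 3' of the minus-strand site
      # is its start: facing means plus site lies left of minus site
      if (plus$end > minus$start) next
      len <- minus$end - plus$start + 1L
      if (len > max_product) next
      out <- rbind(out, data.frame(start = plus$start, end = minus$end,
                                   length = len, strand = a$strand))
    }
  }
  out
}

new_orientation_call <- function(state, evidence, method, note = NULL) {
  structure(list(state = state, evidence = evidence, method = method,
                 note = note), class = "orientation_call")
}

#' @export
print.orientation_call <- function(x, ...) {
  cat(sprintf("Orientation call: %s (method: %s)\n", x$state, x$method))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  ev <- x$evidence
  if (is.data.frame(ev)) {
    print(ev, row.names = FALSE)
  } else if (length(ev)) {
    cat("  evidence:", paste(names(ev), ev, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Call FF orientation from a PCR panel on one or more templates
#'
#' Runs the four panel reactions against the supplied template(s) (several
#' templates model a mixture, e.g. the two haplotypes of a heterozygote).
#' Products from reactions {1,2} only indicate REF; {3,4} only indicate INV;
#' all four indicate a REF/INV heterozygote; any partial or contradictory
#' combination yields AMBIGUOUS with the per-reaction evidence attached.
#'
#' @param templates Character vector of template sequences, or a single
#'   `locus_sequence`.
#' @param panel A [make_primer_panel()] panel.
#' @return An `orientation_call` with per-reaction product counts as
#'   evidence.
#' @export
pcr_panel_call <- function(templates, panel) {
  stopifnot(inherits(panel, "primer_panel"))
  if (inherits(templates, "locus_sequence")) templates <- templates$seq
  products <- vapply(panel$pairs, function(pr) {
    sum(vapply(templates, function(tp) {
      nrow(insilico_pcr(tp, panel$primers[[pr[1]]], panel$primers[[pr[2]]],
                        panel$max_product, panel$max_mismatch))
    }, integer(1)))
  }, integer(1))
  names(products) <- paste0("pcr", 1:4)
  ref_ok <- products[1] > 0 && products[2] > 0
  inv_ok <- products[3] > 0 && products[4] > 0
  any_ref <- products[1] > 0 || products[2] > 0
  any_inv <- products[3] > 0 || products[4] > 0
  state <- if (ref_ok && inv_ok) "HET"
  else if (ref_ok && !any_inv) "REF"
  else if (inv_ok && !any_ref) "INV"
  else "AMBIGUOUS"
  new_orientation_call(state, products, "pcr")
}

#' Call FF orientation from an assembled sequence
#'
#' Locates the four panel anchors in the assembly (either strand) and scores
#' marker adjacency across each IR: outer-left adjacent to inner-left and
#' inner-right adjacent to outer-right indicates REF; outer-left adjacent to
#' inner-right and inner-left adjacent to outer-right indicates INV. The two
#' sides are called independently; disagreement or missing anchors yield
#' AMBIGUOUS with a diagnostic rather than an error. The call is invariant
#' to reverse-complementing the assembly.
#'
#' @param assembly Assembly sequence (character scalar or `locus_sequence`).
#' @param panel A [make_primer_panel()] panel.
#' @return An `orientation_call` with per-side adjacency evidence.
#' @export
call_orientation_assembly <- function(assembly, panel) {
  stopifnot(inherits(panel, "primer_panel"))
  if (inherits(assembly, "locus_sequence")) assembly <- assembly$seq
  pos <- lapply(panel$primers, function(p) {
    s <- primer_sites(assembly, p, panel$max_mismatch)
    if (is.null(s) || nrow(s) == 0L) NULL else (s$start + s$end) / 2
  })
  missing <- names(pos)[vapply(pos, is.null, logical(1))]
  if (length(missing)) {
    return(new_orientation_call(
      "AMBIGUOUS", c(ref_left = 0L, inv_left = 0L, ref_right = 0L,
                     inv_right = 0L),
      "assembly", paste("anchor(s) not found:",
                        paste(missing, collapse = ", "))))
  }
  adjacent <- function(a, b) {
    any(abs(outer(pos[[a]], pos[[b]], "-")) <= panel$max_product)
  }
  ev <- c(ref_left = adjacent("outer_left", "inner_left"),
          inv_left = adjacent("outer_left", "inner_right"),
          ref_right = adjacent("inner_right", "outer_right"),
          inv_right = adjacent("inner_left", "outer_right"))
  side_call <- function(ref, inv) {
    if (ref && !inv) "REF" else if (inv && !ref) "INV" else "AMBIGUOUS"
  }
  left <- side_call(ev["ref_left"], ev["inv_left"])
  right <- side_call(ev["ref_right"], ev["inv_right"])
  state <- if (left == right && left != "AMBIGUOUS") left else "AMBIGUOUS"
  note <- if (state == "AMBIGUOUS") {
    sprintf("left side: %s, right side: %s", left, right)
  }
  new_orientation_call(state, stats::setNames(as.integer(ev), names(ev)),
                       "assembly", note)
}

#' Junction reference sequences for read-level orientation calling
#'
#' Builds IR-spanning junction references for each orientation: for each IR
#' copy, the full repeat plus `anchor` bp of single-copy sequence on both
#' sides (outer flank on one side, FF-region sequence on the other). Both
#' IR/single-copy junctions of the copy are therefore covered by one
#' reference. Because the two IR copies are near-exact reverse complements
#' of each other, a window around a single boundary does not discriminate
#' orientation on a double-stranded read -- the REF inner junction reads as
#' the reverse complement of an INV junction -- so an informative read must
#' span an entire IR and anchor in the single-copy sequence on both sides.
#'
#' @param ref A REF-orientation `locus_sequence`.
#' @param anchor Single-copy anchor length on each side of the IR
#'   (default 200).
#' @return Named character vector of 4 junction references
#'   (`REF_left`, `REF_right`, `INV_left`, `INV_right`), each of length
#'   `ir_length + 2 * anchor`.
#' @export
junction_references <- function(ref, anchor = 200) {
  stopifnot(inherits(ref, "locus_sequence"), ref$orientation == "REF")
  iv <- ref$layout$intervals
  inv <- apply_orientation(ref, "INV")$seq
  span <- function(seq, ir) substr(seq, ir[1] - anchor + 1L, ir[2] + anchor)
  out <- c(
    REF_left = span(ref$seq, iv$irl),
    REF_right = span(ref$seq, iv$irr),
    INV_left = span(inv, iv$irl),
    INV_right = span(inv, iv$irr)
  )
  attr(out, "anchor") <- anchor
  out
}

#' Call FF orientation from sequencing reads
#'
#' Assigns each read to at most one junction class: a read supports a class
#' when it contains, on either strand, the class's discriminating core --
#' the full IR plus `overlap` bp of single-copy sequence on each side -- as
#' an exact substring. Reads shorter than an IR cannot span one, receive no
#' assignment, and leave the call AMBIGUOUS (geometric impossibility, not
#' an error). REF-only support of at least `min_support` reads calls REF;
#' INV-only calls INV; both at least `min_support` call HET; anything less
#' is AMBIGUOUS.
#'
#' @param reads Character vector of read sequences.
#' @param junction_refs Output of [junction_references()].
#' @param min_support Minimum supporting reads per orientation (default 3).
#' @param overlap Required single-copy overlap beyond the IR on each side
#'   (default 50; at most the anchor length used in
#'   [junction_references()]).
#' @return An `orientation_call` with per-side REF/INV junction read counts.
#' @export
call_orientation_reads <- function(reads, junction_refs, min_support = 3,
                                   overlap = 50) {
  if (length(reads) == 0L) {
    return(new_orientation_call(
      "AMBIGUOUS",
      data.frame(side = c("left", "right"), ref = 0L, inv = 0L),
      "reads", "empty read set"))
  }
  expected <- c("REF_left", "REF_right", "INV_left", "INV_right")
  if (!all(expected %in% names(junction_refs))) {
    stop("'junction_refs' must contain ", paste(expected, collapse = ", "))
  }
  anchor <- attr(junction_refs, "anchor", exact = TRUE)
  junction_refs <- junction_refs[expected]
  if (length(unique(nchar(junction_refs))) != 1L) {
    stop("junction references must have equal length")
  }
  # require 'overlap' bp of single-copy context beyond the IR on each side
  core <- if (!is.null(anchor) && overlap < anchor) {
    trim <- anchor - overlap
    vapply(junction_refs, function(j) {
      substr(j, trim + 1L, nchar(j) - trim)
    }, "")
  } else junction_refs
  counts <- stats::setNames(integer(length(core)), names(core))
  for (r in reads) {
    rc <- revcomp(r)
    hit <- vapply(core, function(cs) {
      grepl(cs, r, fixed = TRUE) || grepl(cs, rc, fixed = TRUE)
    }, logical(1))
    counts[hit] <- counts[hit] + 1L
  }
  ev <- data.frame(
    side = c("left", "right"),
    ref = as.integer(counts[c("REF_left", "REF_right")]),
    inv = as.integer(counts[c("INV_left", "INV_right")])
  )
  ref_n <- sum(ev$ref)
  inv_n <- sum(ev$inv)
  state <- if (ref_n >= min_support && inv_n >= min_support) "HET"
  else if (ref_n >= min_support && inv_n == 0L) "REF"
  else if (inv_n >= min_support && ref_n == 0L) "INV"
  else "AMBIGUOUS"
  note <- if (ref_n + inv_n == 0L) {
    "no IR-spanning reads (reads shorter than the IR cannot be informative)"
  }
  new_orientation_call(state, ev, "reads", note)
}

#' Tabulate orientation calls with percentages
#'
#' Counts calls per state and reports percentages rounded to the nearest
#' integer, half away from zero -- the convention that reproduces printed
#' population splits such as 39/50/11.
#'
#' @param calls A character vector of states, a list of `orientation_call`
#'   objects, or a named count vector (e.g. `c(REF = 14, INV = 18, HET = 4)`).
#' @return Data frame with `state`, `count`, `percent`.
#' @export
tabulate_calls <- function(calls) {
  if (is.numeric(calls)) {
    counts <- calls
  } else {
    states <- if (is.list(calls)) {
      vapply(calls, function(x) {
        if (inherits(x, "orientation_call")) x$state else as.character(x)
      }, "")
    } else as.character(calls)
    if (length(states) == 0L) stop("no calls to tabulate")
    counts <- table(states)
  }
  if (sum(counts) == 0) stop("no calls to tabulate")
  order_states <- c("REF", "INV", "HET", "AMBIGUOUS")
  nm <- names(counts)
  nm <- c(intersect(order_states, nm), setdiff(nm, order_states))
  counts <- counts[nm]
  pct <- floor(100 * as.numeric(counts) / sum(counts) + 0.5)
  data.frame(state = nm, count = as.integer(counts), percent = as.integer(pct),
             row.names = NULL)
}
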