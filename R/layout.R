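#' Coordinate model of the flip/flop locus
#'
#' Builds a parametric coordinate layout for a locus in which a central
#' "flip/flop" (FF) region is flanked by two inverted-repeat copies (IRL on
#' the left, IRR on the right), with single-copy flanking DNA on either side.
#' The centromere lies to the right of IRR, so IRR is always the
#' centromere-proximal copy. All internal coordinates are 0-based half-open
#' intervals in locus coordinates; [format_interval()] renders them 1-based
#' inclusive for reports.
#'
#' Each IR carries three sub-features in IRL orientation: a tRNA gene at its
#' left edge, a "centroid" sporulation gene, and a transmembrane-protein (tm)
#' gene. The IR proper begins `ir_start_offset_from_trna` bp after the tRNA
#' gene ends and ends `ir_end_offset_after_tm_stop` bp after the tm gene's
#' stop codon; in IRR the sub-features are mirrored and strand-flipped. When
#' `ir_length` is too short to hold the protein-coding genes (e.g. a minimal
#' 74-bp tRNA-only IR) the gene sub-intervals are dropped.
#'
#' Four marker intervals act as anchor/primer landing sites for orientation
#' assays: `outer_left_marker` and `outer_right_marker` in the single-copy
#' flanks, and `inner_left_marker` / `inner_right_marker` just inside the FF
#' boundaries (proxies for SIW14 and ARK1).
#'
#' @param overrides Named list of parameter overrides. Recognised names:
#'   `ir_length`, `ff_length`, `flank_length`, `marker_length`,
#'   `marker_gap`, `trna_length`, `ir_start_offset_from_trna`,
#'   `ir_end_offset_after_tm_stop`, `centroid_length`, `tm_length`,
#'   `cen_offset`.
#' @return An object of class `ff_layout`: a list with the scalar parameters,
#'   an `intervals` list of 0-based half-open `c(start, end)` pairs
#'   (`outer_left_marker`, `irl`, `ff`, `irr`, `outer_right_marker`,
#'   `inner_left_marker`, `inner_right_marker`), relative IR sub-intervals
#'   (`ir_genes`), the centromere midpoint position `cen_pos` (locus
#'   coordinates, beyond the realized sequence for default parameters) and
#'   `total_length`.
#' @examples
#' lay <- build_default_layout()
#' lay$total_length            # 42400
#' build_default_layout(list(ir_length = 74))  # minimal tRNA-only IR
#' @export
build_default_layout <- function(overrides = list()) {
  p <- list(
    ir_length = 4200,
    ff_length = 24000,
    flank_length = 5000,
    marker_length = 500,
    marker_gap = 200,
    trna_length = 74,
    ir_start_offset_from_trna = 10,
    ir_end_offset_after_tm_stop = 217,
    centroid_length = 1839,
    tm_length = 855,
    cen_offset = 26000
  )
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad)) {
      stop("unknown layout parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(overrides)] <- overrides
  }
  for (nm in c("ir_length", "ff_length", "flank_length", "marker_length")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0) {
      stop("layout parameter '", nm, "' must be a positive scalar")
    }
  }
  if (p$ir_start_offset_from_trna >= p$ir_length ||
      p$ir_end_offset_after_tm_stop >= p$ir_length) {
    stop("IR offsets ('ir_start_offset_from_trna', 'ir_end_offset_after_tm_stop') ",
         "must be smaller than 'ir_length'")
  }
  if (p$trna_length > p$ir_length) {
    stop("'trna_length' exceeds 'ir_length'")
  }
  if (2 * (p$marker_length + p$marker_gap) > p$flank_length) {
    stop("'marker_length' + 'marker_gap' too large for 'flank_length'")
  }
  if (2 * (p$marker_length + p$marker_gap) > p$ff_length) {
    stop("'marker_length' + 'marker_gap' too large for 'ff_length'")
  }

  irl_start <- p$flank_length
  irl_end <- irl_start + p$ir_length
  ff_start <- irl_end
  ff_end <- ff_start + p$ff_length
  irr_start <- ff_end
  irr_end <- irr_start + p$ir_length
  total <- 2 * p$flank_length + 2 * p$ir_length + p$ff_length

  intervals <- list(
    outer_left_marker = c(irl_start - p$marker_gap - p$marker_length,
                          irl_start - p$marker_gap),
    irl = c(irl_start, irl_end),
    inner_left_marker = c(ff_start + p$marker_gap,
                          ff_start + p$marker_gap + p$marker_length),
    ff = c(ff_start, ff_end),
    inner_right_marker = c(ff_end - p$marker_gap - p$marker_length,
                           ff_end - p$marker_gap),
    irr = c(irr_start, irr_end),
    outer_right_marker = c(irr_end + p$marker_gap,
                           irr_end + p$marker_gap + p$marker_length)
  )

  # IR sub-features, relative to the IR start (IRL orientation).
  trna <- c(0, p$trna_length)
  centroid_start <- p$trna_length + p$ir_start_offset_from_trna
  tm_end <- p$ir_length - p$ir_end_offset_after_tm_stop
  ir_genes <- list(trna = trna)
  if (centroid_start + p$centroid_length < tm_end - p$tm_length) {
    ir_genes$centroid <- c(centroid_start, centroid_start + p$centroid_length)
    ir_genes$tm <- c(tm_end - p$tm_length, tm_end)
  }

  layout <- structure(
    c(p, list(
      intervals = intervals,
      ir_genes = ir_genes,
      cen_pos = irr_end + p$cen_offset,
      total_length = total
    )),
    class = "ff_layout"
  )
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  iv <- layout$intervals
  stopifnot(all(vapply(iv, length, 1L) == 2L))
  if (diff(iv$irl) != layout$ir_length || diff(iv$irr) != layout$ir_length) {
    stop("IRL and IRR intervals must both have length 'ir_length'")
  }
  if (diff(iv$ff) != layout$ff_length) {
    stop("FF interval length must equal 'ff_length'")
  }
  # ordering / disjointness along the locus
  ord <- rbind(iv$outer_left_marker, iv$irl, iv$inner_left_marker,
               iv$inner_right_marker, iv$irr, iv$outer_right_marker)
  if (any(ord[, 1] >= ord[, 2])) stop("degenerate interval in layout")
  ends <- ord[-nrow(ord), 2]
  starts <- ord[-1, 1]
  if (any(starts < ends)) stop("layout intervals overlap or are out of order")
  if (layout$cen_pos <= iv$irr[2]) {
    stop("centromere ('cen_pos') must lie to the right of IRR")
  }
  for (g in layout$ir_genes) {
    if (g[1] < 0 || g[2] > layout$ir_length) {
      stop("IR sub-interval exceeds 'ir_length'")
    }
  }
  invisible(layout)
}

#' @export
print.ff_layout <- function(x, ...) {
  cat("Flip/flop locus layout\n")
  cat(sprintf("  IRs: %d bp, FF region: %d bp, flanks: %d bp; total %d bp\n",
              x$ir_length, x$ff_length, x$flank_length, x$total_length))
  cat(sprintf("  centromere midpoint at %s (IRR is centromere-proximal)\n",
              format(x$cen_pos, big.mark = ",")))
  for (nm in names(x$intervals)) {
    cat(sprintf("  %-18s %s\n", nm, format_interval(x$intervals[[nm]])))
  }
  invisible(x)
}

#' Render a 0-based half-open interval as 1-based inclusive text
#'
#' Internal coordinates follow the BED convention (0-based, half-open);
#' user-facing reports use the 1-based inclusive convention of the yeast
#' genome databases.
#'
#' @param interval Numeric `c(start, end)`, 0-based half-open.
#' @return Character scalar like `"101-200"`.
#' @export
format_interval <- function(interval) {
  sprintf("%d-%d", as.integer(interval[1]) + 1L, as.integer(interval[2]))
}

# reverse complement of a plain character DNA string
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Realize a random reference sequence for a layout
#'
#' Draws an i.i.d. nucleotide sequence with the requested GC content, then
#' overwrites the IRR interval with the reverse complement of the IRL
#' interval so that at realization time the two IR copies are exact reverse
#' complements. The result is tagged with orientation `REF`.
#'
#' @param layout An `ff_layout`.
#' @param gc_fraction GC content, strictly between 0 and 1.
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return An object of class `locus_sequence`: list with `seq` (character
#'   scalar over ACGT), `layout`, `orientation` (`"REF"`), and `annotations`
#'   (data frame with `name`, `start`, `end`, `strand`; 0-based half-open).
#' @export
realize_reference <- function(layout, gc_fraction = 0.38, seed = 1L) {
  stopifnot(inherits(layout, "ff_layout"))
  if (!(gc_fraction > 0 && gc_fraction < 1)) {
    stop("'gc_fraction' must be strictly between 0 and 1")
  }
  set.seed(as.integer(seed))
  prob <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
            G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  bases <- sample(names(prob), layout$total_length, replace = TRUE, prob = prob)
  seq <- paste(bases, collapse = "")
  irl <- layout$intervals$irl
  irr <- layout$intervals$irr
  irl_seq <- substr(seq, irl[1] + 1L, irl[2])
  substr(seq, irr[1] + 1L, irr[2]) <- revcomp(irl_seq)

  structure(
    list(seq = seq, layout = layout, orientation = "REF",
         annotations = layout_annotations(layout)),
    class = "locus_sequence"
  )
}

# annotation table (0-based half-open, strand) for a REF-orientation locus
layout_annotations <- function(layout) {
  iv <- layout$intervals
  rows <- list(
    data.frame(name = "outer_left_marker", start = iv$outer_left_marker[1],
               end = iv$outer_left_marker[2], strand = "+"),
    data.frame(name = "IRL", start = iv$irl[1], end = iv$irl[2], strand = "+"),
    data.frame(name = "FF", start = iv$ff[1], end = iv$ff[2], strand = "+"),
    data.frame(name = "inner_left_marker", start = iv$inner_left_marker[1],
               end = iv$inner_left_marker[2], strand = "+"),
    data.frame(name = "inner_right_marker", start = iv$inner_right_marker[1],
               end = iv$inner_right_marker[2], strand = "+"),
    data.frame(name = "IRR", start = iv$irr[1], end = iv$irr[2], strand = "+"),
    data.frame(name = "outer_right_marker", start = iv$outer_right_marker[1],
               end = iv$outer_right_marker[2], strand = "+")
  )
  for (g in names(layout$ir_genes)) {
    rel <- layout$ir_genes[[g]]
    # tRNA is on the minus strand in IRL (and plus in the mirrored IRR copy)
    strand_l <- if (g == "trna") "-" else "+"
    strand_r <- if (strand_l == "+") "-" else "+"
    rows <- c(rows, list(
      data.frame(name = paste0("irl_", g), start = iv$irl[1] + rel[1],
                 end = iv$irl[1] + rel[2], strand = strand_l),
      data.frame(name = paste0("irr_", g), start = iv$irr[2] - rel[2],
                 end = iv$irr[2] - rel[1], strand = strand_r)
    ))
  }
  ann <- do.call(rbind, rows)
  ann[order(ann$start), , drop = FALSE]
}

#' @export
print.locus_sequence <- function(x, ...) {
  cat(sprintf("Locus sequence: %s bp, orientation %s\n",
              format(nchar(x$seq), big.mark = ","), x$orientation))
  cat(sprintf("  %d annotations\n", nrow(x$annotations)))
  invisible(x)
}

#' Set the orientation of a locus sequence
#'
#' Inverts (or restores) the FF region of a realized locus. When the target
#' orientation differs from the current one, the FF interval -- exclusive of
#' the IRs -- is reverse-complemented in place; annotations inside FF get
#' mirrored coordinates and flipped strands. The operation is an involution:
#' applying `INV` then `REF` restores the original sequence.
#'
#' @param locus A `locus_sequence`.
#' @param target `"REF"` or `"INV"`. `HET`/`AMBIGUOUS` are call outputs, not
#'   haplotype states, and are rejected.
#' @return The locus with the requested orientation.
#' @export
apply_orientation <- function(locus, target) {
  stopifnot(inherits(locus, "locus_sequence"))
  if (!is.character(target) || length(target) != 1L ||
      !target %in% c("REF", "INV")) {
    stop("'target' must be \"REF\" or \"INV\"")
  }
  if (target == locus$orientation) return(locus)
  ff <- locus$layout$intervals$ff
  ff_seq <- substr(locus$seq, ff[1] + 1L, ff[2])
  substr(locus$seq, ff[1] + 1L, ff[2]) <- revcomp(ff_seq)
  ann <- locus$annotations
  inside <- ann$start >= ff[1] & ann$end <= ff[2] & ann$name != "FF"
  if (any(inside)) {
    s <- ann$start[inside]
    e <- ann$end[inside]
    ann$start[inside] <- ff[1] + ff[2] - e
    ann$end[inside] <- ff[1] + ff[2] - s
    ann$strand[inside] <- ifelse(ann$strand[inside] == "+", "-", "+")
  }
  locus$annotations <- ann[order(ann$start), , drop = FALSE]
  locus$orientation <- target
  locus
}

#' Write a locus sequence as FASTA plus BED annotations
#'
#' @param locus A `locus_sequence`.
#' @param fasta_path,bed_path Output file paths; `NULL` skips that file.
#' @param name Sequence name used in both files.
#' @return Invisibly, the paths written.
#' @export
write_locus <- function(locus, fasta_path = NULL, bed_path = NULL,
                        name = "locus") {
  stopifnot(inherits(locus, "locus_sequence"))
  if (!is.null(fasta_path)) {
    x <- Biostrings::DNAStringSet(locus$seq)
    names(x) <- name
    Biostrings::writeXStringSet(x, fasta_path)
  }
  if (!is.null(bed_path)) {
    ann <- locus$annotations
    bed <- data.frame(chrom = name, start = ann$start, end = ann$end,
                      name = ann$name, score = 0L, strand = ann$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(fasta = fasta_path, bed = bed_path))
}
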