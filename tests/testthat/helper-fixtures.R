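# Shared fixtures: a small locus keeps sequence-level tests fast, the
# default-size locus is used where the real geometry matters.

small_layout <- function() {
  build_default_layout(list(
    ir_length = 400, ff_length = 2000, flank_length = 800,
    marker_length = 80, marker_gap = 40, trna_length = 20,
    centroid_length = 150, tm_length = 60,
    ir_end_offset_after_tm_stop = 30, cen_offset = 1500
  ))
}

default_locus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- realize_reference(build_default_layout(), gc_fraction = 0.38,
                                  seed = 20260922)
    }
    cache
  }
})

# brute-force minimum-change oracle: enumerate all internal labelings
fitch_oracle <- function(tree, tip_states) {
  tree <- ape::multi2di(tree)
  n_tip <- length(tree$tip.label)
  n_internal <- tree$Nnode
  states <- unique(unname(tip_states))
  if (length(states) == 1L) return(0L)
  node_state <- c(unname(tip_states[tree$tip.label]),
                  rep(NA_character_, n_internal))
  best <- Inf
  for (code in 0:(2^n_internal - 1)) {
    lab <- node_state
    bits <- as.integer(intToBits(code))[seq_len(n_internal)]
    lab[n_tip + seq_len(n_internal)] <- states[bits + 1L]
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# pi by direct per-pair counting over used (non-gap, non-N) sites
pi_oracle <- function(seqs, region = NULL) {
  vecs <- lapply(seqs, function(s) {
    if (inherits(s, "pseudochromosome")) s <- s$seq
    v <- strsplit(s, "")[[1]]
    if (!is.null(region)) v <- v[(region[1] + 1L):region[2]]
    v
  })
  n <- length(vecs)
  ps <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- vecs[[i]]
      b <- vecs[[j]]
      ok <- !(a %in% c("-", "N")) & !(b %in% c("-", "N"))
      ps <- c(ps, sum(a[ok] != b[ok]) / sum(ok))
    }
  }
  c(mean = mean(ps), sd = stats::sd(ps))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
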