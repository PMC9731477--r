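#' Parameters for the IR homogenization / inversion toggling simulator
#'
#' The simulator models the two IR copies of one lineage evolving by
#' per-site substitution (Jukes-Cantor single-nucleotide changes, no
#' indels) and recurrent gene conversion between the copies. Each
#' generation, with probability `g`, one copy (chosen uniformly) is
#' overwritten by the other over a conversion tract; with probability `c`
#' the conversion event is additionally resolved as a crossover, which --
#' because the copies are in inverted orientation -- flips the orientation
#' of the region between them. The default `c = 0.04` is the literature
#' fraction of gene-conversion events resolved as crossovers.
#'
#' @param mu Substitutions per site per generation.
#' @param g Gene-conversion probability per generation.
#' @param c Crossover-resolution probability per conversion (default 0.04).
#' @param tract_model `"whole_ir"` (default; the IRs are homogenized over
#'   their full length) or `"geometric"` (tract start uniform, length
#'   geometric with mean `mean_tract`).
#' @param mean_tract Mean tract length for the geometric model (bp).
#' @param ir_length IR length in bp (default 4200).
#' @param generations Number of generations to simulate.
#' @param seed Integer seed.
#' @return An object of class `toggle_params`.
#' @export
toggle_params <- function(mu = 1e-6, g = 1e-3, c = 0.04,
                          tract_model = c("whole_ir", "geometric"),
                          mean_tract = 1000, ir_length = 4200,
                          generations = 10000, seed = 1L) {
  tract_model <- match.arg(tract_model)
  if (c < 0 || c > 1) stop("'c' must be in [0, 1]")
  if (mu < 0 || g < 0 || g > 1) stop("'mu' must be >= 0 and 'g' in [0, 1]")
  structure(list(mu = mu, g = g, c = c, tract_model = tract_model,
                 mean_tract = mean_tract, ir_length = ir_length,
                 generations = generations, seed = as.integer(seed)),
            class = "toggle_params")
}

mutate_copy <- function(x, mu) {
  n_mut <- stats::rpois(1, mu * length(x))
  if (n_mut > 0) {
    pos <- sample.int(length(x), min(n_mut, length(x)))
    for (p in pos) x[p] <- sample((1:4)[-x[p]], 1)
  }
  x
}

# one generation of toggling dynamics on integer-coded IR copies
toggle_step <- function(state, params) {
  state$irl <- mutate_copy(state$irl, params$mu)
  state$irr <- mutate_copy(state$irr, params$mu)
  if (stats::runif(1) < params$g) {
    state$conversions <- state$conversions + 1L
    recipient <- sample(c("irl", "irr"), 1)
    donor <- if (recipient == "irl") "irr" else "irl"
    if (params$tract_model == "whole_ir") {
      state[[recipient]] <- state[[donor]]
    } else {
      L <- length(state$irl)
      len <- min(L, 1L + stats::rgeom(1, 1 / params$mean_tract))
      start <- sample.int(L - len + 1L, 1)
      idx <- start:(start + len - 1L)
      state[[recipient]][idx] <- state[[donor]][idx]
    }
    if (stats::runif(1) < params$c) {
      state$flips <- state$flips + 1L
      state$orientation <- if (state$orientation == "REF") "INV" else "REF"
    }
  }
  state
}

new_toggle_state <- function(ir_length, orientation = "REF",
                             irl = NULL, irr = NULL) {
  if (is.null(irl)) irl <- sample.int(4L, ir_length, replace = TRUE)
  if (is.null(irr)) irr <- irl
  list(irl = irl, irr = irr, orientation = orientation,
       conversions = 0L, flips = 0L)
}

#' Run the inversion-toggling simulator for one lineage
#'
#' @param params A [toggle_params()] object.
#' @return An object of class `toggle_trajectory`: `trajectory` (data frame
#'   with one row per generation: `generation`, `identity` IRL-vs-IRR,
#'   `orientation`, `conversions`, `flips`), `irl_seq`, `irr_seq` (final
#'   sequences), and `params`.
#' @export
run_toggling <- function(params) {
  stopifnot(inherits(params, "toggle_params"))
  set.seed(params$seed)
  state <- new_toggle_state(params$ir_length)
  n <- params$generations
  identity <- numeric(n)
  orientation <- character(n)
  conversions <- integer(n)
  flips <- integer(n)
  for (t in seq_len(n)) {
    state <- toggle_step(state, params)
    identity[t] <- mean(state$irl == state$irr)
    orientation[t] <- state$orientation
    conversions[t] <- state$conversions
    flips[t] <- state$flips
  }
  bases <- c("A", "C", "G", "T")
  structure(list(
    trajectory = data.frame(generation = seq_len(n), identity = identity,
                            orientation = orientation,
                            conversions = conversions, flips = flips),
    irl_seq = paste(bases[state$irl], collapse = ""),
    irr_seq = paste(bases[state$irr], collapse = ""),
    params = params
  ), class = "toggle_trajectory")
}

#' @export
print.toggle_trajectory <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf(paste0("Toggling trajectory: %d generations, %d conversions, ",
                     "%d flips\n  final IRL/IRR identity %.4f, ",
                     "orientation %s\n"),
              nrow(x$trajectory), last$conversions, last$flips,
              last$identity, last$orientation))
  invisible(x)
}

#' Expected neutral divergence between unconverted IR copies
#'
#' Poisson approximation `1 - exp(-2 * mu * t)` for the proportion of
#' diverged sites between two copies after `t` generations without gene
#' conversion. Back-mutation is ignored, so the approximation is accurate
#' only while `mu * t` is small.
#'
#' @param mu Substitutions per site per generation.
#' @param t Generations.
#' @return Expected proportion of differing sites.
#' @export
expected_divergence_neutral <- function(mu, t) {
  1 - exp(-2 * mu * t)
}

#' Run toggling dynamics along a species tree
#'
#' The locus evolves along every branch of a rooted binary tree with the
#' dynamics of [run_toggling()] (branch lengths are interpreted as
#' generations); lineages split at internal nodes, inheriting the parental
#' IR sequences and orientation. Tips report both IR copies, the
#' orientation, and a truth log of every flip.
#'
#' @param tree An `ape::phylo` tree (or newick string) with branch lengths
#'   in generations.
#' @param params A [toggle_params()]; `generations` is ignored (branch
#'   lengths are used).
#' @return List with `tips` (per-tip list: `irl_seq`, `irr_seq`,
#'   `orientation`), `orientations` (named vector), `flip_log` (data frame:
#'   `edge`, `child`), and `total_flips`.
#' @export
run_species_tree <- function(tree, params) {
  stopifnot(inherits(params, "toggle_params"))
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  set.seed(params$seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  tree <- stats::reorder(tree, "cladewise")
  states <- vector("list", max(tree$edge))
  states[[root]] <- new_toggle_state(params$ir_length)
  flip_log <- list()
  for (i in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[i, 1]
    child <- tree$edge[i, 2]
    st <- states[[parent]]
    flips_before <- st$flips
    gens <- max(0L, round(tree$edge.length[i]))
    for (t in seq_len(gens)) st <- toggle_step(st, params)
    if (st$flips > flips_before) {
      flip_log[[length(flip_log) + 1L]] <- data.frame(
        edge = i, child = child, n_flips = st$flips - flips_before)
    }
    states[[child]] <- st
  }
  bases <- c("A", "C", "G", "T")
  tips <- lapply(seq_len(n_tip), function(i) {
    st <- states[[i]]
    list(irl_seq = paste(bases[st$irl], collapse = ""),
         irr_seq = paste(bases[st$irr], collapse = ""),
         orientation = st$orientation)
  })
  names(tips) <- tree$tip.label
  fl <- if (length(flip_log)) do.call(rbind, flip_log)
  else data.frame(edge = integer(), child = integer(), n_flips = integer())
  list(tips = tips,
       orientations = vapply(tips, `[[`, "", "orientation"),
       flip_log = fl,
       total_flips = sum(fl$n_flips))
}
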