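#' Simulation configuration
#'
#' Defaults describe a typical regional COI barcode library: per-species
#' clusters of near-identical haplotypes (expected within-species pairwise
#' distance 0.6%), sister species a few percent apart (expected between-species
#' distance 5%), a transition/transversion rate ratio of 4, and 658 bp
#' alignments.
#'
#' @param n_species number of species.
#' @param specimens_per_species single integer or per-species vector (1 allowed
#'   -> singleton species).
#' @param seq_length alignment length (default 658).
#' @param interspecific_divergence expected substitutions/site between species
#'   (mean over species pairs; default 0.05).
#' @param intraspecific_divergence expected within-species pairwise distance
#'   (default 0.006).
#' @param kappa transition/transversion rate ratio (default 4).
#' @param introgression_events `NULL` or data.frame with columns `donor`,
#'   `recipient` (species names or 1-based indices) and `n_specimens`: that
#'   many recipient specimens carry a haplotype copied from the donor's pool
#'   (mitochondrial capture -- they keep their recipient species label).
#' @param post_copy_divergence expected distance added to an introgressed copy
#'   (default 0 = identical haplotype).
#' @param n_ambiguous_sites sites replaced by `N` per specimen (default 0).
#' @param seed integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 20, specimens_per_species = 4,
                       seq_length = 658, interspecific_divergence = 0.05,
                       intraspecific_divergence = 0.006, kappa = 4,
                       introgression_events = NULL, post_copy_divergence = 0,
                       n_ambiguous_sites = 0, seed = 1) {
  stopifnot(n_species >= 1, seq_length >= 1, kappa > 0,
            interspecific_divergence > 0, interspecific_divergence < 0.7,
            intraspecific_divergence >= 0, intraspecific_divergence < 0.7)
  if (length(specimens_per_species) == 1L) {
    specimens_per_species <- rep(as.integer(specimens_per_species), n_species)
  }
  stopifnot(length(specimens_per_species) == n_species, all(specimens_per_species >= 1))
  if (intraspecific_divergence >= interspecific_divergence) {
    warning("intraspecific divergence >= interspecific: species clusters will overlap",
            call. = FALSE)
  }
  if (!is.null(introgression_events)) {
    stopifnot(all(c("donor", "recipient", "n_specimens") %in% names(introgression_events)),
              all(introgression_events$donor != introgression_events$recipient))
  }
  structure(list(n_species = as.integer(n_species),
                 specimens_per_species = specimens_per_species,
                 seq_length = as.integer(seq_length),
                 interspecific_divergence = interspecific_divergence,
                 intraspecific_divergence = intraspecific_divergence,
                 kappa = kappa,
                 introgression_events = introgression_events,
                 post_copy_divergence = post_copy_divergence,
                 n_ambiguous_sites = as.integer(n_ambiguous_sites),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# K2P substitution probabilities along a branch of expected length d
# (substitutions/site) with ts/tv rate ratio kappa. With alpha/beta the
# transition/transversion rates and t the time, d = (alpha + 2 beta) t:
#   P(transition)        = 1/4 + 1/4 e^{-4 beta t} - 1/2 e^{-2(alpha+beta) t}
#   P(transversion, sum) = 1/2 - 1/2 e^{-4 beta t}
k2p_branch_probs <- function(d, kappa) {
  bt <- d / (kappa + 2)
  at <- kappa * bt
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.5 - 0.5 * exp(-4 * bt)
  c(ts = p_ts, tv = p_tv)
}

# Evolve an integer-coded sequence (1..4) along one branch.
evolve_codes <- function(codes, d, kappa) {
  if (d <= 0) return(codes)
  p <- k2p_branch_probs(d, kappa)
  u <- stats::runif(length(codes))
  ts_partner <- c(3L, 4L, 1L, 2L)  # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)         # a pyrimidine/purine alternative
  tv2 <- c(4L, 3L, 4L, 3L)
  pick_tv2 <- stats::runif(length(codes)) < 0.5
  out <- codes
  is_ts <- u < p["ts"]
  is_tv <- !is_ts & u < p["ts"] + p["tv"]
  out[is_ts] <- ts_partner[codes[is_ts]]
  out[is_tv & !pick_tv2] <- tv1[codes[is_tv & !pick_tv2]]
  out[is_tv & pick_tv2] <- tv2[codes[is_tv & pick_tv2]]
  out
}

#' Simulate a reference library with known ground truth
#'
#' Draws a uniform ancestral sequence, evolves species ancestors along a
#' random coalescent-shaped species tree (equal tip depths) rescaled so the
#' mean tip-to-tip path length equals the interspecific target, then evolves
#' each specimen from its species ancestor along a branch of half the
#' intraspecific target (so the expected distance between two conspecifics
#' matches the target). Substitutions follow the exact K2P process, so
#' realized distances match the estimator's model. Introgression events copy
#' a donor haplotype over a recipient specimen's sequence (label unchanged).
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `library` (a `reference_library`), `truth` (data.frame:
#'   `specimen_id`, `species`, `lineage`), `species_truth` (data.frame:
#'   `species`, `n_specimens`, `expected_monophyletic`) and `species_tree`
#'   (`phylo`, `NULL` for one species).
#' @examples
#' sim <- simulate_library(sim_config(n_species = 5, seed = 7))
#' sim$library
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_species
  L <- config$seq_length
  kappa <- config$kappa
  species <- sprintf("Simulia species%03d", seq_len(ns))
  # Species tree: coalescent topology with equal tip depths. Raw coalescent
  # node heights put some speciations arbitrarily close to the present, which
  # would let intraspecific variation swamp the shallowest species pairs; the
  # heights are therefore compressed into the upper half of the tree depth
  # (min between-species distance >= ~half the mean, mirroring the observed
  # nearest-neighbor floor in real barcode libraries), then the whole tree is
  # rescaled so the mean tip-to-tip distance equals the interspecific target.
  if (ns > 1) {
    tr <- ape::rcoal(ns, tip.label = species)
    depth <- ape::node.depth.edgelength(tr)        # root = 0, tips = D
    D <- max(depth)
    h <- D - depth                                 # height above the tips
    h[seq_len(ns)] <- 0
    h[-seq_len(ns)] <- D / 2 + h[-seq_len(ns)] / 2
    tr$edge.length <- h[tr$edge[, 1]] - h[tr$edge[, 2]]
    coph <- ape::cophenetic.phylo(tr)
    scale <- config$interspecific_divergence / mean(coph[upper.tri(coph)])
    tr$edge.length <- tr$edge.length * scale
  } else tr <- NULL
  root_seq <- sample.int(4L, L, replace = TRUE)
  anc <- matrix(0L, ns, L)
  if (ns == 1) {
    anc[1, ] <- root_seq
  } else {
    # preorder walk from the root
    node_seq <- vector("list", ns + tr$Nnode)
    node_seq[[ns + 1L]] <- root_seq
    ord <- reorder(tr, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
      node_seq[[ch]] <- evolve_codes(node_seq[[p]], ord$edge.length[e], kappa)
    }
    for (i in seq_len(ns)) anc[i, ] <- node_seq[[i]]
  }
  nspec <- config$specimens_per_species
  total <- sum(nspec)
  seq_mat <- matrix(0L, total, L)
  sp_lab <- rep(species, nspec)
  ids <- sprintf("SIM%04d", seq_len(total))
  row <- 0L
  for (i in seq_len(ns)) {
    for (j in seq_len(nspec[i])) {
      row <- row + 1L
      seq_mat[row, ] <- evolve_codes(anc[i, ], config$intraspecific_divergence / 2, kappa)
    }
  }
  lineage <- rep("native", total)
  ev <- config$introgression_events
  if (!is.null(ev)) {
    for (r in seq_len(nrow(ev))) {
      donor <- resolve_species(ev$donor[r], species)
      recip <- resolve_species(ev$recipient[r], species)
      donor_rows <- which(sp_lab == donor)
      recip_rows <- which(sp_lab == recip)
      n_ev <- ev$n_specimens[r]
      if (n_ev > length(recip_rows)) {
        stop_ba("introgression event %d wants %d specimens but '%s' has %d",
                r, n_ev, recip, length(recip_rows), class = "input_error")
      }
      for (j in seq_len(n_ev)) {
        src <- donor_rows[sample.int(length(donor_rows), 1L)]
        dst <- recip_rows[j]
        s <- seq_mat[src, ]
        if (config$post_copy_divergence > 0) {
          s <- evolve_codes(s, config$post_copy_divergence, kappa)
        }
        seq_mat[dst, ] <- s
        lineage[dst] <- paste0("introgressed-from-", donor)
      }
    }
  }
  if (config$n_ambiguous_sites > 0) {
    for (r in seq_len(total)) {
      seq_mat[r, sample.int(L, config$n_ambiguous_sites)] <- 0L
    }
  }
  seqs <- decode_sequences(seq_mat)
  regions <- c("Jura", "Plateau", "Northern Alps", "Western Alps",
               "Eastern Alps", "Southern Alps")
  md <- data.frame(specimen_id = ids, species = sp_lab,
                   sex = sample(c("male", "female"), total, replace = TRUE),
                   region = sample(regions, total, replace = TRUE),
                   stringsAsFactors = FALSE)
  lib <- new_reference_library(ids, setNames(seqs, ids), md)
  truth <- data.frame(specimen_id = ids, species = sp_lab, lineage = lineage,
                      stringsAsFactors = FALSE)
  affected <- if (is.null(ev)) character(0) else {
    unique(c(vapply(ev$donor, resolve_species, character(1), species = species),
             vapply(ev$recipient, resolve_species, character(1), species = species)))
  }
  species_truth <- data.frame(species = species, n_specimens = nspec,
                              expected_monophyletic = !(species %in% affected),
                              stringsAsFactors = FALSE)
  list(library = lib, truth = truth, species_truth = species_truth,
       species_tree = tr)
}

resolve_species <- function(x, species) {
  if (is.numeric(x)) species[as.integer(x)] else as.character(x)
}

#' Compare realized simulation statistics with their targets
#'
#' Reports the realized mean of per-species maximum intraspecific divergence
#' and the mean nearest-neighbor distance (percent), with the configured
#' targets, plus the overall transition/transversion count ratio against its
#' kappa-implied expectation.
#'
#' @param sim the list returned by [simulate_library()].
#' @param config the [sim_config()] used.
#' @param dm optional precomputed `k2p_dist` for `sim$library`.
#' @return list of diagnostics.
#' @export
summary_check <- function(sim, config, dm = NULL) {
  lib <- sim$library
  if (is.null(dm)) dm <- k2p_matrix(lib, min_overlap = 1)
  intra <- intraspecific_stats(dm, lib)
  nn <- nearest_neighbor(dm, lib)
  m <- encode_sequences(lib$records$sequence, lib$records$specimen_id)
  # pooled transition/transversion counts across all pairs
  X <- lapply(1:4, function(b) (m == b) * 1)
  t_ag <- tcrossprod(X[[1]], X[[3]]); t_ct <- tcrossprod(X[[2]], X[[4]])
  S <- t_ag + t(t_ag) + t_ct + t(t_ct)
  V <- X[[1]] + X[[2]] + X[[3]] + X[[4]]
  sites <- tcrossprod(V)
  matches <- Reduce(`+`, lapply(X, tcrossprod))
  W <- sites - matches - S
  ut <- upper.tri(S)
  list(mean_max_intra = attr(intra, "mean_of_max"),
       target_intra = 100 * config$intraspecific_divergence,
       mean_nn_distance = mean(nn$nn_distance),
       target_inter = 100 * config$interspecific_divergence,
       ts_tv_ratio = sum(S[ut]) / sum(W[ut]),
       n_shared_barcode_species = sum(lengths(nn$shares_barcode_with) > 0))
}
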