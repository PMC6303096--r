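#' Per-species intraspecific divergence
#'
#' Maximum and mean K2P distance over all unordered conspecific pairs, in
#' percent. Singletons get `NA`. If a conspecific pair is undefined
#' (saturated), the species is flagged and its stats use the defined pairs
#' only, with a warning.
#'
#' @param dm a `k2p_dist`.
#' @param lib the `reference_library` the matrix was computed from.
#' @return data.frame with columns `species`, `n_specimens`, `max_intra`,
#'   `mean_intra` (percent), `n_undefined_pairs`. Attribute `mean_of_max` is
#'   the library-level mean of per-species maxima over species with >= 2
#'   records.
#' @export
intraspecific_stats <- function(dm, lib) {
  stopifnot(inherits(dm, "k2p_dist"), inherits(lib, "reference_library"))
  idx <- species_index(lib)
  out <- data.frame(species = names(idx), n_specimens = unname(lengths(idx)),
                    max_intra = NA_real_, mean_intra = NA_real_,
                    n_undefined_pairs = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(idx)) {
    ids <- idx[[k]]
    if (length(ids) < 2L) next
    sub <- dm$distance[ids, ids]
    vals <- sub[upper.tri(sub)]
    n_und <- sum(is.na(vals))
    if (n_und > 0) {
      warning(sprintf("species '%s': %d undefined conspecific pair(s); stats use defined pairs",
                      names(idx)[k], n_und), call. = FALSE)
      vals <- vals[!is.na(vals)]
    }
    out$n_undefined_pairs[k] <- n_und
    if (length(vals)) {
      out$max_intra[k] <- 100 * max(vals)
      out$mean_intra[k] <- 100 * mean(vals)
    }
  }
  attr(out, "mean_of_max") <- mean(out$max_intra[out$n_specimens >= 2], na.rm = TRUE)
  out
}

#' Nearest non-conspecific neighbor per species
#'
#' For each species, the minimum K2P distance over all heterospecific record
#' pairs, the species attaining it (ties: all tied species, lexicographic
#' first as primary), and the set of species sharing a barcode (heterospecific
#' distance exactly zero under pairwise deletion -- identical barcodes, N-containing
#' sequences included).
#'
#' @inheritParams intraspecific_stats
#' @return data.frame with `species`, `nearest_neighbor`,
#'   `nn_distance` (percent), `nn_ties` (comma-joined tied species), and a
#'   list-column `shares_barcode_with`.
#' @export
nearest_neighbor <- function(dm, lib) {
  stopifnot(inherits(dm, "k2p_dist"), inherits(lib, "reference_library"))
  idx <- species_index(lib)
  if (length(idx) < 2L) stop_ba("need at least 2 species", class = "input_error")
  sp_of <- setNames(lib$records$species, lib$records$specimen_id)
  species <- names(idx)
  nn_sp <- character(length(species)); nn_d <- numeric(length(species))
  ties <- character(length(species))
  shares <- vector("list", length(species))
  for (k in seq_along(species)) {
    ids <- idx[[k]]
    others <- setdiff(dm$labels, ids)
    sub <- dm$distance[ids, others, drop = FALSE]
    if (all(is.na(sub))) {
      stop_ba("species '%s': all heterospecific distances undefined", species[k],
              class = "undefined_distance_error")
    }
    dmin <- min(sub, na.rm = TRUE)
    at <- which(sub == dmin, arr.ind = TRUE)
    tied_sp <- sort(unique(sp_of[others[at[, 2]]]))
    nn_sp[k] <- tied_sp[1]
    nn_d[k] <- 100 * dmin
    ties[k] <- paste(tied_sp, collapse = ",")
    zero <- which(sub == 0, arr.ind = TRUE)
    shares[[k]] <- sort(unique(sp_of[others[zero[, 2]]]))
  }
  out <- data.frame(species = species, nearest_neighbor = nn_sp,
                    nn_distance = nn_d, nn_ties = ties, stringsAsFactors = FALSE)
  out$shares_barcode_with <- shares
  out
}

#' Classify species monophyly on an NJ tree
#'
#' A species with one record is `singleton`. A species is `monophyletic` iff
#' some edge of the unrooted tree induces a bipartition with exactly its
#' specimens on one side. Otherwise, on the midpoint-rooted tree, the species
#' is `paraphyletic` if the foreign specimens nested inside the smallest
#' clade containing it form exactly one clade (so that pruning that foreign
#' clade restores monophyly), else `polyphyletic`.
#'
#' @param tree an unrooted `phylo` whose leaves are the library specimen ids.
#' @param lib the `reference_library`.
#' @return data.frame with `species`, `monophyly` (factor: monophyletic,
#'   paraphyletic, polyphyletic, singleton) and a list-column `entangled_with`
#'   (the species whose specimens interleave with the focal species; empty for
#'   monophyletic and singleton species).
#' @export
classify_monophyly <- function(tree, lib) {
  stopifnot(inherits(tree, "phylo"), inherits(lib, "reference_library"))
  if (!setequal(tree$tip.label, lib$records$specimen_id)) {
    stop_ba("tree leaves do not match library specimen ids", class = "input_error")
  }
  idx <- species_index(lib)
  sp_of <- setNames(lib$records$species, lib$records$specimen_id)
  all_tips <- tree$tip.label
  # An unrooted tree (the NJ case) is judged by bipartitions: a clade OR its
  # complement may delimit the species, and para/polyphyly is resolved on the
  # midpoint rooting. A tree supplied already rooted keeps its rooting and is
  # judged on clades only.
  input_rooted <- ape::is.rooted(tree)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  clade_sets <- lapply(pp, function(i) labs[i])
  clade_keys <- vapply(clade_sets, function(s) paste(sort(s), collapse = "|"), character(1))
  comp_keys <- if (input_rooted) character(0) else {
    vapply(clade_sets, function(s) paste(sort(setdiff(all_tips, s)), collapse = "|"),
           character(1))
  }
  status <- character(length(idx))
  entangled <- rep(list(character(0)), length(idx))
  rooted <- if (input_rooted) tree else NULL
  for (k in seq_along(idx)) {
    ids <- idx[[k]]
    if (length(ids) == 1L) { status[k] <- "singleton"; next }
    key <- paste(sort(ids), collapse = "|")
    if (key %in% clade_keys || key %in% comp_keys) { status[k] <- "monophyletic"; next }
    if (is.null(rooted)) rooted <- midpoint_root(tree)
    mrca <- ape::getMRCA(rooted, ids)
    clade <- desc_tips(rooted, mrca)
    foreign <- setdiff(clade, ids)
    entangled[[k]] <- sort(unique(sp_of[foreign]))
    # paraphyletic iff the foreign specimens form exactly one nested clade
    # (pruning that clade then restores monophyly); otherwise polyphyletic
    f_mrca <- if (length(foreign) == 1L) NULL else ape::getMRCA(rooted, foreign)
    f_clade <- if (is.null(f_mrca)) foreign else desc_tips(rooted, f_mrca)
    status[k] <- if (setequal(f_clade, foreign)) "paraphyletic" else "polyphyletic"
  }
  out <- data.frame(species = names(idx),
                    monophyly = factor(status, levels = c("monophyletic", "paraphyletic",
                                                          "polyphyletic", "singleton")),
                    stringsAsFactors = FALSE)
  out$entangled_with <- entangled
  out
}

#' Run the full per-species audit
#'
#' Assembles the per-species assessment table: intraspecific divergence,
#' nearest neighbor, shared barcodes, monophyly, the two diagnosability
#' criteria, and cryptic-diversity flags.
#'
#' Diagnosability: `cluster_diagnostic` follows the barcode-cluster criterion
#' (monophyletic and sharing no barcode, or a singleton whose nearest neighbor
#' is non-zero); `haplotype_diagnostic` follows the species-specific-haplotype
#' criterion (no shared barcode, regardless of monophyly), so the cluster
#' criterion is always at least as strict.
#'
#' @param lib a `reference_library`.
#' @param dm optional precomputed `k2p_dist` (default `k2p_matrix(lib, ...)`).
#' @param tree optional precomputed NJ `phylo` (default `nj_build(dm)`).
#' @param min_overlap minimum comparable sites for distances.
#' @param cryptic_thresholds percent thresholds for cryptic-diversity flags;
#'   a species is flagged when `max_intra` is strictly greater ("over 2%").
#' @return An `audit_report`: list with `assessments` (one row per species),
#'   `summary` (library-level counts, percentages, means) and `params`.
#' @export
species_audit <- function(lib, dm = NULL, tree = NULL, min_overlap = 100,
                          cryptic_thresholds = c(2, 3)) {
  stopifnot(inherits(lib, "reference_library"))
  if (is.null(dm)) dm <- k2p_matrix(lib, min_overlap = min_overlap)
  if (is.null(tree)) tree <- nj_build(dm)
  intra <- intraspecific_stats(dm, lib)
  nn <- nearest_neighbor(dm, lib)
  mono <- classify_monophyly(tree, lib)
  # all three tables come from species_index() and share its (sorted) order
  stopifnot(identical(intra$species, nn$species), identical(intra$species, mono$species))
  a <- cbind(intra, nn[, setdiff(names(nn), "species"), drop = FALSE],
             mono[, setdiff(names(mono), "species"), drop = FALSE])
  n_shares <- lengths(a$shares_barcode_with)
  a$cluster_diagnostic <- (a$monophyly == "monophyletic" & n_shares == 0L) |
    (a$monophyly == "singleton" & a$nn_distance > 0)
  a$haplotype_diagnostic <- n_shares == 0L
  for (thr in cryptic_thresholds) {
    a[[sprintf("cryptic_flag_%gpct", thr)]] <-
      !is.na(a$max_intra) & a$max_intra > thr
  }
  n_sp <- nrow(a)
  mono_counts <- table(a$monophyly)
  summary <- list(
    n_species = n_sp,
    n_specimens = nrow(lib$records),
    monophyly_counts = as.list(mono_counts),
    monophyly_pct = lapply(as.list(mono_counts), function(x) 100 * x / n_sp),
    n_cluster_diagnostic = sum(a$cluster_diagnostic),
    pct_cluster_diagnostic = 100 * sum(a$cluster_diagnostic) / n_sp,
    n_haplotype_diagnostic = sum(a$haplotype_diagnostic),
    pct_haplotype_diagnostic = 100 * sum(a$haplotype_diagnostic) / n_sp,
    mean_max_intra = attr(intra, "mean_of_max"),
    mean_nn_distance = mean(a$nn_distance),
    cryptic_counts = setNames(
      lapply(cryptic_thresholds,
             function(thr) sum(a[[sprintf("cryptic_flag_%gpct", thr)]])),
      sprintf("over_%gpct", cryptic_thresholds))
  )
  structure(list(assessments = a, summary = summary,
                 params = list(min_overlap = min_overlap,
                               cryptic_thresholds = cryptic_thresholds)),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Barcode library audit: %d species, %d specimens\n",
              s$n_species, s$n_specimens))
  mc <- s$monophyly_counts
  cat(sprintf("  monophyletic %d | paraphyletic %d | polyphyletic %d | singleton %d\n",
              mc$monophyletic, mc$paraphyletic, mc$polyphyletic, mc$singleton))
  cat(sprintf("  cluster-diagnostic: %d (%.1f%%); haplotype-diagnostic: %d (%.1f%%)\n",
              s$n_cluster_diagnostic, round_half_up(s$pct_cluster_diagnostic, 1),
              s$n_haplotype_diagnostic, round_half_up(s$pct_haplotype_diagnostic, 1)))
  invisible(x)
}

#' Cryptic-diversity flags
#'
#' Flags species whose maximum intraspecific divergence is strictly greater
#' than each threshold ("over 2%" is a strict inequality; singletons are never
#' flagged).
#'
#' @param assessments the `assessments` data.frame of an [species_audit()]
#'   report (needs `species` and `max_intra`).
#' @param thresholds percent thresholds (default `c(2, 3)`).
#' @return data.frame: `species`, one logical column per threshold.
#' @export
cryptic_flags <- function(assessments, thresholds = c(2, 3)) {
  out <- data.frame(species = assessments$species, stringsAsFactors = FALSE)
  for (thr in thresholds) {
    out[[sprintf("over_%gpct", thr)]] <-
      !is.na(assessments$max_intra) & assessments$max_intra > thr
  }
  out
}

#' Identify a query sequence against a reference library
#'
#' Nearest-record identification: returns the species of the nearest reference
#' record if its distance is at or below `threshold` and no second species
#' lies within `tie_margin` of that distance. Exact ties across species yield
#' an ambiguous identification listing the tied species.
#'
#' @param query an aligned sequence string of the library's alignment length.
#' @param lib a `reference_library`.
#' @param threshold maximum acceptable nearest distance, percent (default 2).
#' @param tie_margin extra distance (percent) within which a second species
#'   makes the call ambiguous; default 0 = exact ties only.
#' @param min_overlap minimum comparable sites per comparison.
#' @return list with `status` ("match", "ambiguous" or "no_match"), `species`
#'   (character vector: the match, the tied set, or empty), `distance`
#'   (percent to the nearest record) and `nearest_record`.
#' @export
identify_query <- function(query, lib, threshold = 2, tie_margin = 0,
                           min_overlap = 100) {
  stopifnot(inherits(lib, "reference_library"))
  if (nrow(lib$records) == 0L) stop_ba("empty reference library", class = "input_error")
  query <- normalize_sequences(query, "query")
  if (nchar(query) != lib$alignment_length) {
    stop_ba("query length %d != alignment length %d", nchar(query),
            lib$alignment_length, class = "alignment_length_error")
  }
  d <- vapply(lib$records$sequence, function(s) {
    p <- k2p_distance(query, s, min_overlap = min_overlap)
    if (p$low_overlap || is.na(p$distance)) NA_real_ else p$distance * 100
  }, numeric(1), USE.NAMES = FALSE)
  if (all(is.na(d))) {
    return(list(status = "no_match", species = character(0),
                distance = NA_real_, nearest_record = NA_character_))
  }
  dmin <- min(d, na.rm = TRUE)
  if (dmin > threshold) {
    return(list(status = "no_match", species = character(0), distance = dmin,
                nearest_record = lib$records$specimen_id[which.min(d)]))
  }
  within <- !is.na(d) & d <= dmin + tie_margin
  sp <- sort(unique(lib$records$species[within]))
  status <- if (length(sp) == 1L) "match" else "ambiguous"
  list(status = status, species = sp, distance = dmin,
       nearest_record = lib$records$specimen_id[which.min(d)])
}
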