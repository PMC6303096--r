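#' Kimura 2-parameter distance between two aligned sequences
#'
#' Comparable sites are the positions where both sequences carry an
#' unambiguous base (A, C, G or T); all other columns are excluded for this
#' pair (pairwise deletion). Over comparable sites, `P` is the proportion of
#' transitions (A<->G, C<->T), `Q` the proportion of transversions (all other
#' mismatches), and
#' \deqn{d = -\tfrac{1}{2}\,\ln\!\big((1-2P-Q)\sqrt{1-2Q}\big).}
#' When the log arguments are non-positive the distance is saturated and
#' returned as `NA` (never clamped: a clamp would corrupt nearest-neighbor
#' minima downstream).
#'
#' @param seq_a,seq_b aligned nucleotide strings of equal length (uppercase
#'   over A,C,G,T,N,-).
#' @param min_overlap minimum number of comparable sites below which the pair
#'   is flagged as having insufficient overlap (default 100, conservative for
#'   a 658 bp barcode).
#' @return A list of class `k2p_pair`: `comparable_sites`, `transitions`,
#'   `transversions`, `P`, `Q`, `distance` (substitutions/site, `NA` if
#'   saturated or no comparable sites), `saturated`, `low_overlap`.
#' @examples
#' k2p_distance("ACGTACGTAC", "ACGTACGTAT", min_overlap = 5)$distance
#' @export
k2p_distance <- function(seq_a, seq_b, min_overlap = 100) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop_ba("sequences differ in length (%d vs %d)", nchar(seq_a), nchar(seq_b),
            class = "alignment_length_error")
  }
  m <- encode_sequences(c(a = seq_a, b = seq_b))
  comparable <- m[1, ] > 0L & m[2, ] > 0L
  a <- m[1, comparable]; b <- m[2, comparable]
  nsite <- length(a)
  diff <- a != b
  # purines (A=1, G=3) are odd codes, pyrimidines (C=2, T=4) even
  ts <- sum(diff & (a %% 2L == b %% 2L))
  tv <- sum(diff) - ts
  P <- if (nsite > 0) ts / nsite else NA_real_
  Q <- if (nsite > 0) tv / nsite else NA_real_
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- if (nsite > 0 && !is.na(w1) && w1 > 0 && w2 > 0) {
    -0.5 * log(w1) - 0.25 * log(w2)
  } else NA_real_
  structure(list(comparable_sites = nsite, transitions = ts, transversions = tv,
                 P = P, Q = Q, distance = d,
                 saturated = nsite > 0 && is.na(d),
                 low_overlap = nsite < min_overlap),
            class = "k2p_pair")
}

#' Full K2P distance matrix for a library
#'
#' Computes every unordered pair under pairwise deletion. Implemented with
#' indicator-matrix cross-products so the whole matrix costs a handful of
#' `tcrossprod` calls rather than an explicit pair loop.
#'
#' @param lib a `reference_library` with at least 2 records.
#' @param min_overlap minimum comparable sites per pair; pairs below it are
#'   reported in `low_overlap_pairs` (an error in strict mode).
#' @param strict if `TRUE`, any low-overlap pair is a fatal error.
#' @return A `k2p_dist`: list with `labels`, `distance` (symmetric matrix in
#'   substitutions/site, zero diagonal, `NA` for saturated/undefined pairs),
#'   `sites` (comparable-site counts), `undefined_pairs` and
#'   `low_overlap_pairs` (2-column character matrices), `min_overlap`.
#' @export
k2p_matrix <- function(lib, min_overlap = 100, strict = FALSE) {
  stopifnot(inherits(lib, "reference_library"))
  rec <- lib$records
  if (nrow(rec) < 2L) stop_ba("library has fewer than 2 records", class = "input_error")
  m <- encode_sequences(rec$sequence, rec$specimen_id)
  X <- lapply(1:4, function(b) (m == b) * 1)
  V <- X[[1]] + X[[2]] + X[[3]] + X[[4]]
  sites <- tcrossprod(V)                      # comparable sites per pair
  matches <- Reduce(`+`, lapply(X, tcrossprod))
  t_ag <- tcrossprod(X[[1]], X[[3]])
  t_ct <- tcrossprod(X[[2]], X[[4]])
  S <- t_ag + t(t_ag) + t_ct + t(t_ct)        # transitions
  W <- sites - matches - S                    # transversions
  P <- S / sites
  Q <- W / sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- suppressWarnings(-0.5 * log(w1) - 0.25 * log(w2))
  d[!is.finite(d)] <- NA_real_
  d[sites == 0] <- NA_real_
  diag(d) <- 0
  labels <- rec$specimen_id
  dimnames(d) <- dimnames(sites) <- list(labels, labels)
  und <- which(upper.tri(d) & is.na(d), arr.ind = TRUE)
  undefined_pairs <- cbind(labels[und[, 1]], labels[und[, 2]])
  low <- which(upper.tri(sites) & sites < min_overlap, arr.ind = TRUE)
  low_overlap_pairs <- cbind(labels[low[, 1]], labels[low[, 2]])
  if (strict && nrow(low_overlap_pairs) > 0) {
    stop_ba("%d pair(s) below minimum overlap of %d sites (first: %s / %s)",
            nrow(low_overlap_pairs), min_overlap,
            low_overlap_pairs[1, 1], low_overlap_pairs[1, 2],
            class = "overlap_error")
  }
  structure(list(labels = labels, distance = d, sites = sites,
                 undefined_pairs = undefined_pairs,
                 low_overlap_pairs = low_overlap_pairs,
                 min_overlap = min_overlap),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat(sprintf("K2P distance matrix: %d labels, %d undefined pair(s), %d low-overlap pair(s)\n",
              length(x$labels), nrow(x$undefined_pairs), nrow(x$low_overlap_pairs)))
  invisible(x)
}

#' @export
as.matrix.k2p_dist <- function(x, ...) x$distance

#' Export a distance matrix as TSV (percent units)
#'
#' Square TSV with specimen ids as header row and first column; distances as
#' percent with 4 decimals; `NA` for undefined pairs.
#'
#' @param dm a `k2p_dist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  stopifnot(inherits(dm, "k2p_dist"))
  pct <- dm$distance * 100
  txt <- matrix(sprintf("%.4f", pct), nrow = nrow(pct))
  txt[is.na(pct)] <- "NA"
  out <- cbind(specimen_id = dm$labels, txt)
  colnames(out) <- c("specimen_id", dm$labels)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
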