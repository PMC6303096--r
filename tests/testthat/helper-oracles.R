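# Independent oracles and fixture builders. These deliberately avoid the
# package's own vectorized code paths: the K2P oracle is a per-site character
# loop, the distance/NN oracles are plain double loops.

oracle_k2p <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  acgt <- c("A", "C", "G", "T")
  keep <- av %in% acgt & bv %in% acgt
  av <- av[keep]; bv <- bv[keep]
  n <- length(av)
  ts <- 0L; tv <- 0L
  for (i in seq_len(n)) {
    if (av[i] != bv[i]) {
      purine_a <- av[i] %in% c("A", "G")
      purine_b <- bv[i] %in% c("A", "G")
      if (purine_a == purine_b) ts <- ts + 1L else tv <- tv + 1L
    }
  }
  P <- if (n) ts / n else NA_real_
  Q <- if (n) tv / n else NA_real_
  d <- if (n && (1 - 2 * P - Q) > 0 && (1 - 2 * Q) > 0) {
    -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  } else NA_real_
  list(n = n, ts = ts, tv = tv, P = P, Q = Q, d = d)
}

# Build a reference_library directly from vectors (no files).
make_lib <- function(species, seqs, ids = sprintf("id%03d", seq_along(seqs))) {
  md <- data.frame(specimen_id = ids, species = species, sex = "unknown",
                   region = NA_character_, stringsAsFactors = FALSE)
  barcodeaudit:::new_reference_library(ids, stats::setNames(seqs, ids), md)
}

# Random aligned sequences with optional ambiguous characters.
random_seqs <- function(n, len, p_ambig = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    if (p_ambig > 0) {
      k <- stats::rbinom(1, len, p_ambig)
      if (k > 0) x[sample.int(len, k)] <- sample(c("N", "-"), k, replace = TRUE)
    }
    paste(x, collapse = "")
  }, character(1))
}

write_fixture_fasta <- function(ids, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

write_fixture_tsv <- function(ids, species, path = tempfile(fileext = ".tsv"),
                              sex = NULL, region = NULL) {
  df <- data.frame(specimen_id = ids, species = species, stringsAsFactors = FALSE)
  if (!is.null(sex)) df$sex <- sex
  if (!is.null(region)) df$region <- region
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Fake k2p_dist from a plain percent-free matrix (substitutions/site).
fake_dm <- function(mat) {
  structure(list(labels = rownames(mat), distance = mat,
                 sites = matrix(658L, nrow(mat), ncol(mat), dimnames = dimnames(mat)),
                 undefined_pairs = matrix(character(0), 0, 2),
                 low_overlap_pairs = matrix(character(0), 0, 2),
                 min_overlap = 100),
            class = "k2p_dist")
}

# unique: rooting duplicates the root split across the two root-child clades
split_keys <- function(tree) {
  sort(unique(as.character(stats::na.omit(barcodeaudit:::tree_splits(tree)))))
}
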