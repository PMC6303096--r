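#' Assemble a reference library from FASTA and metadata
#'
#' Reads an aligned FASTA file plus a tab-separated metadata table and returns
#' a validated `reference_library`. Sequences are uppercased, `U` is mapped to
#' `T`, and IUPAC ambiguity codes other than `N` are mapped to `N` (with a
#' warning): the distance machinery treats every non-ACGT character
#' identically under pairwise deletion, so nothing is lost. Inputs must be
#' pre-aligned: all sequences are required to share one alignment length
#' (COI barcodes are indel-free in practice, so no aligner is wrapped here).
#'
#' @param path path to a FASTA file (single-line or wrapped).
#' @param metadata path to a UTF-8 TSV with a header row; required columns
#'   `specimen_id` and `species`, optional `sex` (`male`/`female`/`unknown`)
#'   and `region`.
#' @return A `reference_library`: list with `records` (data.frame with columns
#'   `specimen_id`, `species`, `sex`, `region`, `sequence`, in FASTA file
#'   order) and `alignment_length`.
#' @examples
#' fa <- tempfile(fileext = ".fasta"); md <- tempfile(fileext = ".tsv")
#' writeLines(c(">s1", "ACGTACGTAC", ">s2", "ACGTACGTAA"), fa)
#' writeLines(c("specimen_id\tspecies", "s1\tAglais io", "s2\tAglais io"), md)
#' lib <- read_fasta(fa, md)
#' lib$alignment_length
#' @export
read_fasta <- function(path, metadata) {
  if (!file.exists(path)) stop_ba("FASTA file not found: %s", path, class = "io_error")
  if (file.size(path) == 0L) {
    stop_ba("empty input: FASTA file '%s' contains no sequences", path, class = "empty_input_error")
  }
  dna <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_ba("cannot parse FASTA '%s': %s", path,
                                              conditionMessage(e), class = "fasta_parse_error"))
  if (length(dna) == 0L) {
    stop_ba("empty input: FASTA file '%s' contains no sequences", path, class = "empty_input_error")
  }
  seqs <- as.character(dna)
  ids <- sub("\\s.*$", "", names(seqs))  # id = first whitespace-delimited token
  names(seqs) <- ids
  md <- read_metadata(metadata)
  new_reference_library(ids, seqs, md)
}

read_metadata <- function(path) {
  if (!file.exists(path)) stop_ba("metadata file not found: %s", path, class = "io_error")
  md <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8")
  required <- c("specimen_id", "species")
  missing <- setdiff(required, names(md))
  if (length(missing)) {
    stop_ba("metadata TSV lacks required column(s): %s",
            paste(missing, collapse = ", "), class = "metadata_error")
  }
  if (!"sex" %in% names(md)) md$sex <- "unknown"
  if (!"region" %in% names(md)) md$region <- NA_character_
  md$sex[is.na(md$sex) | md$sex == ""] <- "unknown"
  bad_sex <- setdiff(unique(md$sex), c("male", "female", "unknown"))
  if (length(bad_sex)) {
    stop_ba("invalid sex value(s): %s", paste(bad_sex, collapse = ", "),
            class = "metadata_error")
  }
  md
}

# Construct and validate; shared by read_fasta and the simulator.
new_reference_library <- function(ids, seqs, md) {
  if (anyDuplicated(ids)) {
    stop_ba("duplicated specimen id(s) in FASTA: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            class = "metadata_error")
  }
  seqs <- normalize_sequences(seqs, ids)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    tab <- table(lens)
    major <- as.integer(names(tab)[which.max(tab)])
    off <- ids[lens != major]
    stop_ba("alignment-length error: sequences are not all the same length (%s); offending id(s): %s",
            paste(names(tab), collapse = " vs "), paste(off, collapse = ", "),
            class = "alignment_length_error")
  }
  no_base <- !grepl("[ACGT]", seqs)
  if (any(no_base)) {
    stop_ba("sequence(s) with no unambiguous base: %s",
            paste(ids[no_base], collapse = ", "), class = "sequence_error")
  }
  orphan <- setdiff(ids, md$specimen_id)
  if (length(orphan)) {
    stop_ba("metadata-join error: %d FASTA id(s) missing from metadata: %s",
            length(orphan), paste(orphan, collapse = ", "),
            class = "metadata_join_error")
  }
  md <- md[match(ids, md$specimen_id), , drop = FALSE]
  records <- data.frame(specimen_id = ids,
                        species = md$species,
                        sex = md$sex,
                        region = md$region,
                        sequence = unname(seqs),
                        stringsAsFactors = FALSE,
                        row.names = NULL)
  structure(list(records = records,
                 alignment_length = unname(lens[1])),
            class = "reference_library")
}

normalize_sequences <- function(seqs, ids) {
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  ambig <- "RYSWKMBDHV"
  has_ambig <- grepl(sprintf("[%s]", ambig), seqs)
  if (any(has_ambig)) {
    warning(sprintf("IUPAC ambiguity codes mapped to N in %d sequence(s): %s",
                    sum(has_ambig), paste(ids[has_ambig], collapse = ", ")),
            call. = FALSE)
    seqs <- chartr(ambig, strrep("N", nchar(ambig)), seqs)
  }
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop_ba("invalid sequence character(s) in: %s",
            paste(ids[bad], collapse = ", "), class = "sequence_error")
  }
  seqs
}

#' @export
print.reference_library <- function(x, ...) {
  idx <- species_index(x)
  cat(sprintf("Reference library: %d records, %d species, alignment length %d\n",
              nrow(x$records), length(idx), x$alignment_length))
  n1 <- sum(lengths(idx) == 1L)
  if (n1) cat(sprintf("  singleton species: %d\n", n1))
  invisible(x)
}

#' Species index of a library
#'
#' @param lib a `reference_library`.
#' @return Named list mapping each species to its specimen ids (the partition
#'   of records by species label; trinomials are distinct labels).
#' @export
species_index <- function(lib) {
  stopifnot(inherits(lib, "reference_library"))
  split(lib$records$specimen_id, lib$records$species)
}

#' Species represented by a single sequence
#' @param lib a `reference_library`.
#' @return Character vector of singleton species names.
#' @export
singleton_species <- function(lib) {
  idx <- species_index(lib)
  names(idx)[lengths(idx) == 1L]
}

#' Write a library back to FASTA + metadata TSV
#'
#' Inverse of [read_fasta()]: `read_fasta(fasta, metadata)` after
#' `write_library()` reproduces ids, species and sequences exactly.
#'
#' @param lib a `reference_library`.
#' @param fasta,metadata output paths.
#' @return `lib`, invisibly.
#' @export
write_library <- function(lib, fasta, metadata) {
  stopifnot(inherits(lib, "reference_library"))
  rec <- lib$records
  writeLines(paste0(">", rec$specimen_id, "\n", rec$sequence), fasta)
  utils::write.table(rec[, c("specimen_id", "species", "sex", "region")],
                     metadata, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(lib)
}

#' Subset a library to a set of specimens
#' @param lib a `reference_library`.
#' @param ids specimen ids to keep (order preserved from the library).
#' @return A `reference_library` with the selected records.
#' @export
subset_library <- function(lib, ids) {
  keep <- lib$records$specimen_id %in% ids
  out <- lib
  out$records <- lib$records[keep, , drop = FALSE]
  row.names(out$records) <- NULL
  out
}

#' Read a newick tree
#'
#' Thin wrapper over ape's parser with the package's contract: missing branch
#' lengths become 0 and numeric internal labels are bootstrap supports.
#'
#' @param path path to a file whose contents are a newick string ending in ';'.
#' @return An ape `phylo` tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  open <- gregexpr("(", txt, fixed = TRUE)[[1]]
  close <- gregexpr(")", txt, fixed = TRUE)[[1]]
  n_open <- sum(open > 0); n_close <- sum(close > 0)
  if (n_open != n_close) {
    off <- if (n_open > n_close) max(open) else max(close)
    stop_ba("newick parse error: unbalanced parentheses near character offset %d", off,
            class = "newick_parse_error")
  }
  if (!grepl(";\\s*$", txt)) {
    stop_ba("newick parse error: string does not end in ';'", class = "newick_parse_error")
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop_ba("newick parse error: %s", conditionMessage(e),
                                               class = "newick_parse_error"))
  if (is.null(tree)) stop_ba("newick parse error", class = "newick_parse_error")
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  tree
}

#' Write a tree as newick
#'
#' Emits standard newick with branch lengths to 6 decimals and any support
#' values (numeric internal node labels) as internal labels, so the file
#' round-trips through [read_newick()] to an isomorphic tree.
#'
#' @param tree an ape `phylo` with >= 2 leaves and non-empty leaf labels.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop_ba("tree has fewer than 2 leaves", class = "tree_error")
  if (any(!nzchar(tree$tip.label))) stop_ba("empty leaf label", class = "tree_error")
  txt <- newick_string(tree)
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_ba("cannot write newick to '%s'", path, class = "io_error")
  invisible(path)
}

# Recursive newick serializer; lengths "%.6f", internal labels verbatim.
newick_string <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  has_len <- !is.null(tree$edge.length)
  lab <- function(node) {
    if (node <= n) return(quote_label(tree$tip.label[node]))
    nl <- tree$node.label
    if (is.null(nl)) return("")
    l <- nl[node - n]
    if (is.na(l) || !nzchar(l)) "" else quote_label(l)
  }
  rec <- function(node) {
    es <- kids[[as.character(node)]]
    if (is.null(es)) return(lab(node))
    parts <- vapply(es, function(e) {
      child <- tree$edge[e, 2]
      s <- rec(child)
      if (has_len) s <- paste0(s, ":", sprintf("%.6f", tree$edge.length[e]))
      s
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")", lab(node))
  }
  paste0(rec(root), ";")
}

quote_label <- function(x) {
  if (grepl("[ ,();:\\[\\]']", x)) {
    paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
  } else x
}
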