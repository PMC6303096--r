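#' Confusability graph
#'
#' Species are nodes; an edge joins two species that cannot reliably be told
#' apart under a given evidence channel (barcode, male morphology, female
#' morphology). Each input group becomes a clique: confusability is symmetric,
#' and "difficult in at least some cases" in either direction counts.
#'
#' @param groups list of character vectors, each a set (>= 2) of mutually
#'   confusable species.
#' @return A `confusability_graph`: list with `edges` (2-column character
#'   matrix, each row a sorted species pair, unique) and `groups`.
#' @export
confusability_graph <- function(groups = list()) {
  edges <- matrix(character(0), 0, 2)
  for (g in groups) {
    g <- unique(g)
    if (length(g) < 2L) stop_ba("confusable group needs >= 2 species", class = "input_error")
    pr <- t(utils::combn(sort(g), 2))
    edges <- rbind(edges, pr)
  }
  edges <- unique(edges)
  if (nrow(edges) && any(edges[, 1] == edges[, 2])) {
    stop_ba("self-edge in confusability graph", class = "input_error")
  }
  structure(list(edges = edges, groups = groups), class = "confusability_graph")
}

#' @export
print.confusability_graph <- function(x, ...) {
  cat(sprintf("Confusability graph: %d edge(s) over %d difficult species\n",
              nrow(x$edges), length(difficult_species(x))))
  invisible(x)
}

#' Edge-wise intersection of two confusability graphs
#'
#' The integrated channel: a pair remains confusable only if it is confusable
#' under both channels.
#'
#' @param a,b `confusability_graph` objects.
#' @return A `confusability_graph` with the intersection edge set.
#' @export
graph_intersect <- function(a, b) {
  stopifnot(inherits(a, "confusability_graph"), inherits(b, "confusability_graph"))
  ka <- pair_key(a$edges[, 1], a$edges[, 2])
  kb <- pair_key(b$edges[, 1], b$edges[, 2])
  keep <- ka %in% kb
  structure(list(edges = a$edges[keep, , drop = FALSE], groups = NULL),
            class = "confusability_graph")
}

#' Species touched by at least one confusion edge
#' @param g a `confusability_graph`.
#' @return Sorted character vector of difficult species.
#' @export
difficult_species <- function(g) {
  stopifnot(inherits(g, "confusability_graph"))
  sort(unique(c(g$edges)))
}

#' Identification-rate table across evidence channels
#'
#' Species-level accounting: a species is "difficult" under a channel if any
#' confusion edge touches it; the always-possible rate is
#' `100 * (n_species - n_difficult) / n_species`. Integrated channels are the
#' edge-wise intersection of the barcode graph with each per-sex morphology
#' graph, so the integrated difficult set is a subset of each parent's and the
#' integrated rate is >= both parents'. Percentages are kept exact internally
#' and rounded half-up to 1 decimal only in the `rate_always` column.
#'
#' @param barcode,male,female `confusability_graph` objects over the same
#'   species universe.
#' @param n_species size of the species universe (denominator).
#' @return An `id_rate_table`: data.frame with one row per channel (`barcode`,
#'   `male_morphology`, `female_morphology`, `integrated_male`,
#'   `integrated_female`) and columns `n_difficult`, `rate_always_exact`,
#'   `rate_always`, `rate_difficult`; attribute `deltas` holds the improvement
#'   of each integrated channel over its parents (computed from the rounded
#'   rates, the way such tables are reported).
#' @export
identification_rates <- function(barcode, male, female, n_species) {
  stopifnot(n_species >= 1)
  chans <- list(barcode = barcode, male_morphology = male,
                female_morphology = female,
                integrated_male = graph_intersect(barcode, male),
                integrated_female = graph_intersect(barcode, female))
  bad <- unlist(lapply(chans, function(g) difficult_species(g)))
  if (length(unique(bad)) > n_species) {
    stop_ba("more difficult species (%d) than the universe (%d)",
            length(unique(bad)), n_species, class = "input_error")
  }
  nd <- vapply(chans, function(g) length(difficult_species(g)), integer(1))
  exact <- 100 * (n_species - nd) / n_species
  out <- data.frame(channel = names(chans), n_difficult = unname(nd),
                    rate_always_exact = unname(exact),
                    rate_always = unname(round_half_up(exact, 1)),
                    rate_difficult = unname(round_half_up(100 - exact, 1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  r <- setNames(out$rate_always, out$channel)
  attr(out, "deltas") <- c(
    integrated_male_vs_barcode = unname(r["integrated_male"] - r["barcode"]),
    integrated_male_vs_morphology = unname(r["integrated_male"] - r["male_morphology"]),
    integrated_female_vs_barcode = unname(r["integrated_female"] - r["barcode"]),
    integrated_female_vs_morphology = unname(r["integrated_female"] - r["female_morphology"]))
  attr(out, "n_species") <- n_species
  class(out) <- c("id_rate_table", "data.frame")
  out
}

#' Read a confusable-groups annotation TSV
#'
#' Expected columns: `channel` (one of `barcode`, `male_morphology`,
#' `female_morphology`), `species` (semicolon-separated group members) and,
#' for barcode groups, logical `shares_barcode` (does the group contain
#' individuals with identical barcodes across species, as opposed to
#' para/polyphyly with species-specific haplotypes). A `note` column is
#' carried along if present. The packaged fixture
#' `system.file("extdata", "swiss_confusable_groups.tsv", package =
#' "barcodeaudit")` transcribes the published Swiss accounting and can be
#' copied and edited for other faunas.
#'
#' @param path TSV path.
#' @param reference_species optional species list; group members absent from
#'   it are an error.
#' @return data.frame with list-column `species` plus `channel`,
#'   `shares_barcode`.
#' @export
read_confusability_groups <- function(path, reference_species = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("channel", "species")
  if (!all(need %in% names(df))) {
    stop_ba("groups TSV needs columns: %s", paste(need, collapse = ", "),
            class = "input_error")
  }
  ok_chan <- c("barcode", "male_morphology", "female_morphology")
  if (!all(df$channel %in% ok_chan)) {
    stop_ba("unknown channel(s): %s",
            paste(setdiff(unique(df$channel), ok_chan), collapse = ", "),
            class = "input_error")
  }
  members <- lapply(strsplit(df$species, ";", fixed = TRUE), trimws)
  if (any(lengths(members) < 2L)) {
    stop_ba("every confusable group needs >= 2 species", class = "input_error")
  }
  if (!is.null(reference_species)) {
    unknown <- setdiff(unlist(members), reference_species)
    if (length(unknown)) {
      stop_ba("group member(s) not in reference species list: %s",
              paste(unknown, collapse = ", "), class = "input_error")
    }
  }
  out <- data.frame(channel = df$channel, stringsAsFactors = FALSE)
  out$species <- members
  out$shares_barcode <- if ("shares_barcode" %in% names(df)) {
    as.logical(df$shares_barcode)
  } else NA
  if ("note" %in% names(df)) out$note <- df$note
  out
}

#' Channel graphs from a confusable-groups table
#'
#' @param groups data.frame from [read_confusability_groups()].
#' @return Named list of `confusability_graph`s: `barcode`, `male_morphology`,
#'   `female_morphology`, plus `barcode_sharing_only` (the barcode groups
#'   whose members actually share haplotypes -- the species-specific-haplotype
#'   criterion drops the non-sharing para/polyphyletic groups from the
#'   difficult set).
#' @export
channel_graphs <- function(groups) {
  by_chan <- function(ch) confusability_graph(groups$species[groups$channel == ch])
  bc <- groups$channel == "barcode"
  list(barcode = by_chan("barcode"),
       male_morphology = by_chan("male_morphology"),
       female_morphology = by_chan("female_morphology"),
       barcode_sharing_only = confusability_graph(
         groups$species[bc & !is.na(groups$shares_barcode) & groups$shares_barcode]))
}

#' Barcode confusability graph from an audit report
#'
#' Edges join species that are mutually entangled on the tree (members of the
#' same para/polyphyletic complex) or that share a barcode.
#'
#' @param audit an `audit_report` from [species_audit()].
#' @return A `confusability_graph`.
#' @export
barcode_graph <- function(audit) {
  stopifnot(inherits(audit, "audit_report"))
  a <- audit$assessments
  groups <- list()
  for (k in seq_len(nrow(a))) {
    sh <- a$shares_barcode_with[[k]]
    for (s in sh) groups[[length(groups) + 1L]] <- c(a$species[k], s)
    # entanglement must be mutual: a monophyletic species that merely sits
    # inside the spanning clade of a polyphyletic one is not confusable
    for (s in a$entangled_with[[k]]) {
      j <- which(a$species == s)
      if (length(j) && a$species[k] %in% a$entangled_with[[j]]) {
        groups[[length(groups) + 1L]] <- c(a$species[k], s)
      }
    }
  }
  confusability_graph(groups)
}

#' Packaged Swiss accounting fixture
#'
#' Loads the transcribed confusable-groups table for the Swiss butterfly and
#' forester-moth reference library (217 sequenced resident species out of a
#' 224-species national list; 868 sequences). The species-level rate
#' denominator is the number of sequenced resident species, 217.
#'
#' @return list with `groups` (see [read_confusability_groups()]),
#'   `n_species` (217), `n_reference_species` (224), `n_sequences` (868).
#' @export
swiss_fixture <- function() {
  path <- system.file("extdata", "swiss_confusable_groups.tsv",
                      package = "barcodeaudit", mustWork = TRUE)
  list(groups = read_confusability_groups(path),
       n_species = 217L, n_reference_species = 224L, n_sequences = 868L)
}
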