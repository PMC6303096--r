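# Internal helpers shared across modules.

# Round half away from zero (the paper-style "91.65 -> 91.7"), unlike base
# round()'s banker's rounding.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Canonical string key for an unordered species pair.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ba <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "barcodeaudit_error")))
}

# Encode aligned sequences as an n x L integer matrix: A=1, C=2, G=3, T=4,
# anything else (N, -, ambiguity) = 0.  Rows named by specimen id.
encode_sequences <- function(seqs, ids = names(seqs)) {
  stopifnot(length(unique(nchar(seqs))) <= 1L)
  chars <- strsplit(seqs, "", fixed = TRUE)
  m <- do.call(rbind, lapply(chars, function(x) {
    v <- match(x, c("A", "C", "G", "T"))
    v[is.na(v)] <- 0L
    v
  }))
  rownames(m) <- ids
  m
}

decode_sequences <- function(mat) {
  alpha <- c("N", "A", "C", "G", "T")
  apply(mat, 1L, function(r) paste(alpha[r + 1L], collapse = ""))
}
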