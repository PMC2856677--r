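# Internal helpers shared across modules.

# Round half away from zero (R's round() is half-to-even). Downstream count
# consumers require deterministic half-up behaviour for replicate means.
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# Reverse complement of a character vector of DNA sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Fast random DNA: one raw draw split into sequences of the given lengths.
random_dna <- function(lens) {
  total <- sum(lens)
  if (total == 0L) return(character(length(lens)))
  big <- rawToChar(as.raw(sample(c(65L, 67L, 71L, 84L), total, replace = TRUE)))
  ends <- cumsum(lens)
  substring(big, ends - lens + 1L, ends)
}

# 1-based start of the terminal poly(A) run if it is at least min_run long,
# otherwise nchar(seq) + 1 (no poly(A); the whole sequence is eligible).
polya_run_start <- function(sequence, min_run = 15L) {
  m <- regexpr("A+$", sequence)
  len <- attr(m, "match.length")
  out <- nchar(sequence) + 1L
  hit <- m > 0L & len >= min_run
  out[hit] <- m[hit]
  out
}

stop_config <- function(...) stop("configuration error: ", ..., call. = FALSE)
stop_input <- function(...) stop("input error: ", ..., call. = FALSE)
stop_degenerate <- function(...) stop("degenerate input: ", ..., call. = FALSE)

check_acgt <- function(sequence, what = "sequence") {
  bad <- grepl("[^ACGT]", sequence)
  if (any(bad)) {
    stop_input(sprintf("%s contains non-ACGT characters (first offender: %s)",
                       what, sequence[which(bad)[1L]]))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
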