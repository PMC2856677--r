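# Shared fixture builders. Everything is generated in code at test time.

# Small, fast simulation settings; override any field via ...
tiny_config <- function(...) {
  defaults <- list(n_genes = 120L, isoform_prob = 0.1, frac_de = 0.1,
                   log2_fc_mean = 2, log2_fc_sd = 0.5, library_size = 3e4,
                   n_replicates_per_stepper = 2L, decoy_frac = 0.05,
                   n_decoys = 10L, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  if (args$n_decoys == 0L && !("decoy_frac" %in% names(list(...))))
    args$decoy_frac <- 0
  do.call(sim_config, args)
}

# Hand-built transcriptome object from explicit sequences/annotation.
make_transcriptome <- function(transcripts, decoys = NULL,
                               signature_length = 21L, polya_min = 15L) {
  transcripts$length <- nchar(transcripts$sequence)
  if (is.null(transcripts$strand)) transcripts$strand <- "+"
  if (is.null(decoys))
    decoys <- data.frame(decoy_id = character(0), sequence = character(0),
                         stringsAsFactors = FALSE)
  structure(list(transcripts = transcripts, decoys = decoys,
                 signature_length = as.integer(signature_length),
                 polya_min = as.integer(polya_min)),
            class = "mpss_transcriptome")
}

# Deterministic G-free filler so the only GATC sites are the planted ones
# (GATC is its own reverse complement, so antisense sites coincide with
# planted sense sites and nowhere else).
filler <- function(n, phase = 0L) {
  alph <- c("C", "T", "A")
  paste(alph[((seq_len(n) + phase) %% 3L) + 1L], collapse = "")
}

# Sequence with GATC planted at given 1-based positions.
plant_gatc <- function(len, at, phase = 0L) {
  s <- filler(len, phase)
  for (p in at) substr(s, p, p + 3L) <- "GATC"
  s
}

# One tag_library from a named count vector.
lib_of <- function(id, condition, stepper, replicate, counts,
                   total = sum(counts)) {
  tag_library(id, condition, stepper, replicate, counts, total)
}

# Valid distinct 21-nt tags for count-table fixtures (GATC + base-4 tail).
fixture_tags <- function(n) {
  vapply(seq_len(n) - 1L, function(i) {
    d <- integer(17L)
    for (k in 1:17) {
      d[k] <- i %% 4L
      i <- i %/% 4L
    }
    paste0("GATC", paste(c("A", "C", "G", "T")[d + 1L], collapse = ""))
  }, "")
}

# Independent reverse complement (kept separate from the package's own).
revcomp_chr <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), "")
}
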