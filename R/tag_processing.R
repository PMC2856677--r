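#' Extract the 3'-most DpnII signature from a sequence
#'
#' MPSS captures, for each transcript, the GATC-anchored fragment closest to
#' the poly(A) tail. This returns `GATC` plus the following
#' `signature_length - 4` bases at the 3'-most GATC whose full signature fits
#' upstream of the terminal poly(A) run (a terminal A-run of at least
#' `polya_min` bases); sequences without a poly(A) run (e.g. genomic decoys)
#' use their full length. Vectorised over `sequence`.
#'
#' @param sequence Character vector of A/C/G/T sequences.
#' @param signature_length Total signature length including GATC (>= 8,
#'   default 21).
#' @param polya_min Minimum terminal A-run recognised as poly(A).
#' @return Character vector of signatures; `NA` where no eligible site
#'   exists.
#' @export
extract_signature <- function(sequence, signature_length = 21L, polya_min = 15L) {
  if (signature_length < 8L) stop_config("signature_length must be >= 8")
  if (length(sequence) == 0L) return(character(0))
  check_acgt(sequence)
  pa <- polya_run_start(sequence, polya_min)
  hits <- gregexpr("GATC", sequence, fixed = TRUE)
  out <- rep(NA_character_, length(sequence))
  for (i in seq_along(sequence)) {
    o <- hits[[i]]
    o <- o[o > 0L & o + signature_length - 1L <= pa[i] - 1L]
    if (length(o)) {
      s <- max(o)
      out[i] <- substr(sequence[i], s, s + signature_length - 1L)
    }
  }
  out
}

#' Build a signature database over a transcriptome
#'
#' Enumerates every GATC-anchored signature on both strands of all annotated
#' transcripts and decoys, marks the sense 3'-most signature per transcript,
#' and assigns each occurrence a mapping class:
#'
#' * class 1 — sense, the 3'-most signature upstream of the annotated end;
#' * class 2 — sense, internal (upstream of the annotated end but not
#'   3'-most);
#' * class 3 — sense, within the 3'-flank window (annotated end to
#'   `flank_bp` beyond it);
#' * class 4 — antisense, within the transcript body;
#' * class 5 — antisense, within the 3'-flank window;
#' * decoy occurrences are recorded as `unannotated`.
#'
#' The class rule table is this package's concretisation of the 1-5 scheme
#' used in the MPSS literature, which is cited rather than restated in the
#' primary sources; treat the exact boundaries as an interpretation.
#'
#' @param transcriptome An `mpss_transcriptome` (or a list with a
#'   `transcripts` data.frame carrying transcript_id, gene_id, sequence,
#'   polya_start and optionally a `decoys` data.frame).
#' @param signature_length Signature length, default 21.
#' @param flank_bp 3'-flank window width in bases, default 1000.
#' @return An object of class `signature_db`: list with `records` (one row
#'   per occurrence: tag, source_id, gene_id, offset (0-based), strand,
#'   is_three_prime_most, category) and a lookup index by tag.
#' @export
build_signature_database <- function(transcriptome, signature_length = 21L,
                                     flank_bp = 1000L) {
  sl <- as.integer(signature_length)
  if (sl < 8L) stop_config("signature_length must be >= 8")
  tx <- transcriptome$transcripts
  dec <- transcriptome$decoys %||% data.frame(decoy_id = character(0),
                                              sequence = character(0))

  rec <- list()
  scan_seq <- function(seq, rcseq, L, pa_start, source_id, gene_id, annotated) {
    out <- list()
    # sense occurrences
    o <- gregexpr("GATC", seq, fixed = TRUE)[[1L]]
    o <- o[o > 0L & o + sl - 1L <= L]
    if (length(o)) {
      body <- o + sl - 1L <= pa_start - 1L
      flank <- !body & o <= pa_start - 1L + flank_bp
      keep <- body | flank
      o <- o[keep]; body <- body[keep]
      if (length(o)) {
        tpm_flag <- body & o == max(c(-Inf, o[body]))
        cat_s <- ifelse(body, ifelse(tpm_flag, "1", "2"), "3")
        if (!annotated) cat_s <- rep("unannotated", length(o))
        out[[length(out) + 1L]] <- data.frame(
          tag = substring(seq, o, o + sl - 1L),
          source_id = source_id, gene_id = gene_id,
          offset = o - 1L, strand = "+",
          is_three_prime_most = annotated & tpm_flag,
          category = cat_s, stringsAsFactors = FALSE)
      }
    }
    # antisense occurrences (signatures on the reverse-complement strand)
    oa <- gregexpr("GATC", rcseq, fixed = TRUE)[[1L]]
    oa <- oa[oa > 0L & oa + sl - 1L <= L]
    if (length(oa)) {
      fstart <- L - (oa + sl - 1L) + 1L      # forward coords of the signature
      fend <- fstart + sl - 1L
      body <- fend <= pa_start - 1L
      flank <- !body & fstart <= pa_start - 1L + flank_bp
      keep <- body | flank
      oa <- oa[keep]; fstart <- fstart[keep]; body <- body[keep]
      if (length(oa)) {
        cat_a <- ifelse(body, "4", "5")
        if (!annotated) cat_a <- rep("unannotated", length(oa))
        out[[length(out) + 1L]] <- data.frame(
          tag = substring(rcseq, oa, oa + sl - 1L),
          source_id = source_id, gene_id = gene_id,
          offset = fstart - 1L, strand = "-",
          is_three_prime_most = FALSE,
          category = cat_a, stringsAsFactors = FALSE)
      }
    }
    out
  }

  if (nrow(tx)) {
    rc <- revcomp(tx$sequence)
    L <- nchar(tx$sequence)
    for (i in seq_len(nrow(tx))) {
      rec <- c(rec, scan_seq(tx$sequence[i], rc[i], L[i], tx$polya_start[i],
                             tx$transcript_id[i], tx$gene_id[i], TRUE))
    }
  }
  if (nrow(dec)) {
    rc <- revcomp(dec$sequence)
    L <- nchar(dec$sequence)
    for (i in seq_len(nrow(dec))) {
      rec <- c(rec, scan_seq(dec$sequence[i], rc[i], L[i], L[i] + 1L,
                             dec$decoy_id[i], NA_character_, FALSE))
    }
  }

  records <- if (length(rec)) do.call(rbind, rec) else
    data.frame(tag = character(0), source_id = character(0),
               gene_id = character(0), offset = integer(0),
               strand = character(0), is_three_prime_most = logical(0),
               category = character(0), stringsAsFactors = FALSE)
  rownames(records) <- NULL
  structure(list(records = records,
                 index = split(seq_len(nrow(records)), records$tag),
                 signature_length = sl, flank_bp = as.integer(flank_bp)),
            class = "signature_db")
}

#' @export
print.signature_db <- function(x, ...) {
  cat(sprintf("signature_db: %d occurrences of %d distinct %d-nt signatures\n",
              nrow(x$records), length(x$index), x$signature_length))
  invisible(x)
}

mapping_categories <- c("1", "2", "3", "4", "5", "unannotated", "multi", "unmapped")

#' Map tags against a signature database and assign classes
#'
#' Per tag: no database hit gives `unmapped`; hits at more than one distinct
#' locus give `multi`; a unique decoy hit gives `unannotated`; a unique
#' annotated hit is classed 1-5 by the database's rule table. Multi-mapping
#' is counted at the locus (gene) level, so two isoforms of the same gene
#' sharing a 3' signature still map uniquely to that gene (best — lowest —
#' class among the gene's occurrences wins).
#'
#' @param tags Character vector of tag sequences (must start with GATC).
#' @param db A [build_signature_database()] result.
#' @return data.frame(tag, tag_class, source_id, gene_id); `tag_class` is a
#'   factor over 1-5, unannotated, multi, unmapped.
#' @export
map_and_classify <- function(tags, db) {
  if (!inherits(db, "signature_db")) stop_input("db must be a signature_db")
  if (length(tags) && any(substr(tags, 1L, 4L) != "GATC"))
    stop_input("all tags must start with GATC")
  cls <- character(length(tags))
  src <- rep(NA_character_, length(tags))
  gene <- rep(NA_character_, length(tags))
  recs <- db$records
  hit_rows <- db$index[tags]
  for (i in seq_along(tags)) {
    rows <- hit_rows[[i]]
    if (is.null(rows)) { cls[i] <- "unmapped"; next }
    h <- recs[rows, , drop = FALSE]
    locus <- ifelse(is.na(h$gene_id), h$source_id, h$gene_id)
    if (length(unique(locus)) > 1L) { cls[i] <- "multi"; next }
    if (all(is.na(h$gene_id))) {
      cls[i] <- "unannotated"
      src[i] <- h$source_id[1L]
      next
    }
    h <- h[order(h$category, h$source_id), , drop = FALSE]
    cls[i] <- h$category[1L]
    src[i] <- h$source_id[1L]
    gene[i] <- h$gene_id[1L]
  }
  data.frame(tag = tags,
             tag_class = factor(cls, levels = mapping_categories),
             source_id = src, gene_id = gene, stringsAsFactors = FALSE)
}

#' Mapping-category fractions
#'
#' Fractions of tags per mapping category (classes 1-5, unannotated, multi,
#' unmapped), optionally weighted (e.g. by tag counts so the fractions refer
#' to sequenced tags rather than distinct sequences). Fractions sum to 1.
#'
#' @param records A [map_and_classify()] result.
#' @param weights Optional nonnegative weights, one per record.
#' @return Named numeric vector over the eight categories.
#' @export
mapping_summary <- function(records, weights = NULL) {
  if (NROW(records) == 0L) stop_degenerate("no records to summarise")
  w <- weights %||% rep(1, nrow(records))
  if (length(w) != nrow(records)) stop_input("weights length mismatch")
  tot <- tapply(w, records$tag_class, sum)
  out <- ifelse(is.na(tot), 0, tot) / sum(w)
  names(out) <- mapping_categories
  out
}
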