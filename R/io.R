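# Tab-delimited readers/writers for the pipeline's stable on-disk formats.
# All column orders are fixed; every writer sorts rows deterministically so
# reruns with the same seed are byte-identical.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a synthetic transcriptome to FASTA + annotation
#'
#' FASTA holds transcript and decoy sequences; the annotation table has the
#' fixed columns transcript_id, gene_id, length, polyA_start, strand.
#'
#' @param transcriptome An `mpss_transcriptome`.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the paths.
#' @export
write_transcriptome <- function(transcriptome, fasta_path, annotation_path) {
  tx <- transcriptome$transcripts
  seqs <- Biostrings::DNAStringSet(c(tx$sequence, transcriptome$decoys$sequence))
  names(seqs) <- c(tx$transcript_id, transcriptome$decoys$decoy_id)
  Biostrings::writeXStringSet(seqs, fasta_path)
  ann <- data.frame(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
                    length = tx$length, polyA_start = tx$polya_start,
                    strand = tx$strand, stringsAsFactors = FALSE)
  write_tsv(ann, annotation_path)
  invisible(c(fasta = fasta_path, annotation = annotation_path))
}

#' Read a transcriptome from FASTA + annotation
#'
#' Sequences named in the annotation become transcripts; any remaining
#' FASTA records are treated as decoys.
#'
#' @param fasta_path,annotation_path Input paths.
#' @param signature_length,polya_min Signature parameters to carry.
#' @return An `mpss_transcriptome`.
#' @export
read_transcriptome <- function(fasta_path, annotation_path,
                               signature_length = 21L, polya_min = 15L) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ann <- read_tsv(annotation_path)
  i <- match(ann$transcript_id, names(seqs))
  if (anyNA(i)) stop_input("annotation references sequences absent from FASTA")
  tx <- data.frame(transcript_id = ann$transcript_id, gene_id = ann$gene_id,
                   sequence = as.character(seqs[i]),
                   length = ann$length, polya_start = ann$polyA_start,
                   strand = ann$strand, stringsAsFactors = FALSE)
  rest <- setdiff(names(seqs), ann$transcript_id)
  decoys <- data.frame(decoy_id = rest,
                       sequence = as.character(seqs[rest]),
                       stringsAsFactors = FALSE)
  structure(list(transcripts = tx, decoys = decoys,
                 signature_length = as.integer(signature_length),
                 polya_min = as.integer(polya_min)),
            class = "mpss_transcriptome")
}

#' Write a set of tag libraries plus manifest
#'
#' Each library becomes `<library_id>.counts.tsv` (columns tag, count,
#' sorted by tag); `manifest.tsv` lists library_id, condition, stepper,
#' replicate, total_tags, file.
#'
#' @param libraries List of [tag_library()] objects.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
write_library_set <- function(libraries, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- do.call(rbind, lapply(libraries, function(l) {
    f <- paste0(l$library_id, ".counts.tsv")
    cnt <- l$counts[order(names(l$counts))]
    write_tsv(data.frame(tag = names(cnt), count = as.integer(cnt),
                         stringsAsFactors = FALSE),
              file.path(dir, f))
    data.frame(library_id = l$library_id, condition = l$condition,
               stepper = l$stepper, replicate = l$replicate,
               total_tags = l$total_tags, file = f, stringsAsFactors = FALSE)
  }))
  man <- man[order(man$library_id), , drop = FALSE]
  write_tsv(man, file.path(dir, "manifest.tsv"))
  invisible(file.path(dir, "manifest.tsv"))
}

#' Read a set of tag libraries from a manifest
#'
#' @param manifest_path Path to a `manifest.tsv` written by
#'   [write_library_set()].
#' @return Named list of [tag_library()] objects.
#' @export
read_library_set <- function(manifest_path) {
  man <- read_tsv(manifest_path)
  dir <- dirname(manifest_path)
  libs <- lapply(seq_len(nrow(man)), function(i) {
    ct <- read_tsv(file.path(dir, man$file[i]))
    counts <- stats::setNames(ct$count, ct$tag)
    tag_library(man$library_id[i], man$condition[i], man$stepper[i],
                man$replicate[i], counts, man$total_tags[i])
  })
  names(libs) <- man$library_id
  libs
}

#' Read GMT-style gene sets
#'
#' One set per line: set name, description, then gene symbols, all
#' tab-separated.
#'
#' @param path Input path.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}

#' Write GMT-style gene sets
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @return Invisibly, the path.
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction edge list
#'
#' Tab-delimited with columns from, relation, to (a header is expected).
#'
#' @param path Input path.
#' @return data.frame(from, relation, to).
#' @export
read_edge_list <- function(path) {
  ed <- read_tsv(path)
  if (!all(c("from", "to") %in% names(ed)))
    stop_input("edge list needs 'from' and 'to' columns")
  if (is.null(ed$relation)) ed$relation <- "interaction"
  ed[, c("from", "relation", "to")]
}
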