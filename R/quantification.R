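#' Construct a tag-count library
#'
#' The basic unit of MPSS quantification: a named vector of tag counts for
#' one sequencing run, labelled by condition, stepper series and replicate
#' index. The stored counts are the nonzero entries; `total_tags` is the
#' sequenced library size and must equal the count sum.
#'
#' @param library_id Unique identifier.
#' @param condition Condition label (e.g. "gbm", "normal").
#' @param stepper One of "2-step", "3-step".
#' @param replicate Replicate index (>= 1).
#' @param counts Named nonnegative integer vector (names are tag sequences).
#' @param total_tags Total sequenced tags; defaults to `sum(counts)`.
#' @return An object of class `tag_library`.
#' @export
tag_library <- function(library_id, condition, stepper, replicate,
                        counts, total_tags = sum(counts)) {
  if (!stepper %in% c("2-step", "3-step"))
    stop_input("stepper must be '2-step' or '3-step'")
  if (is.null(names(counts)) || anyDuplicated(names(counts)))
    stop_input("counts must be uniquely named by tag sequence")
  if (any(counts < 0)) stop_input("counts must be nonnegative")
  if (total_tags <= 0) stop_input("total_tags must be positive")
  counts <- counts[counts > 0]
  if (abs(sum(counts) - total_tags) > 1e-9)
    stop_input("sum of counts must equal total_tags")
  structure(list(library_id = library_id, condition = condition,
                 stepper = stepper, replicate = as.integer(replicate),
                 counts = counts, total_tags = as.numeric(total_tags)),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("tag_library %s [%s %s r%d]: %d distinct tags, %s total\n",
              x$library_id, x$condition, x$stepper, x$replicate,
              length(x$counts), format(x$total_tags, big.mark = ",")))
  invisible(x)
}

#' Merge stepper replicate series into one expression table
#'
#' Implements the stepper-selection rule used for MPSS quantification: per
#' tag, average the counts across the 2-step replicates and across the
#' 3-step replicates, pick the stepper with the higher mean (ties go to
#' 2-step), and let the replicate mean of the chosen stepper represent the
#' tag. The representative count is converted to tags per million (tpm)
#' using the chosen stepper's mean library total:
#' `tpm = 1e6 * mean(count) / mean(total)`.
#'
#' @param libraries List of [tag_library()] objects from a single condition.
#' @return An `expression_table`: data.frame(tag, count, total, stepper,
#'   tpm) sorted by tag, with the condition label as attribute `condition`.
#'   Representative counts are replicate means and need not be integers.
#' @export
merge_steppers <- function(libraries) {
  if (length(libraries) == 0L) stop_degenerate("no libraries supplied")
  conds <- unique(vapply(libraries, function(l) l$condition, ""))
  if (length(conds) != 1L)
    stop_input("merge_steppers expects libraries from a single condition")
  steppers <- vapply(libraries, function(l) l$stepper, "")
  tags <- sort(unique(unlist(lapply(libraries, function(l) names(l$counts)))))

  mean_stat <- function(sel) {
    if (!any(sel)) return(list(count = NULL, total = NA_real_))
    m <- vapply(libraries[sel], function(l) {
      v <- l$counts[tags]
      v[is.na(v)] <- 0
      as.numeric(v)
    }, numeric(length(tags)))
    m <- matrix(m, nrow = length(tags))
    list(count = rowMeans(m),
         total = mean(vapply(libraries[sel], function(l) l$total_tags, 0)))
  }
  s2 <- mean_stat(steppers == "2-step")
  s3 <- mean_stat(steppers == "3-step")
  c2 <- s2$count %||% rep(-Inf, length(tags))
  c3 <- s3$count %||% rep(-Inf, length(tags))

  use2 <- c2 >= c3                       # tie -> 2-step
  count <- ifelse(use2, c2, c3)
  total <- ifelse(use2, s2$total, s3$total)
  out <- data.frame(tag = tags, count = count, total = total,
                    stepper = ifelse(use2, "2-step", "3-step"),
                    tpm = 1e6 * count / total,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "condition") <- conds
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Filter to significantly expressed tags
#'
#' Keeps tags whose tpm exceeds `min_tpm` in at least one of the two
#' condition tables. The default reproduces the ">3 tpm in at least one
#' pool" expression filter; the comparison is strict by default (a tag at
#' exactly 3 tpm is excluded), with `strict = FALSE` for an inclusive bound.
#'
#' @param table_a,table_b `expression_table`s for the two conditions.
#' @param min_tpm Threshold, default 3.
#' @param strict Use `>` (default) rather than `>=`.
#' @return Sorted character vector of retained tag sequences.
#' @export
filter_expressed <- function(table_a, table_b, min_tpm = 3, strict = TRUE) {
  tags <- sort(unique(c(table_a$tag, table_b$tag)))
  ta <- table_a$tpm[match(tags, table_a$tag)]
  tb <- table_b$tpm[match(tags, table_b$tag)]
  ta[is.na(ta)] <- 0
  tb[is.na(tb)] <- 0
  keep <- if (strict) ta > min_tpm | tb > min_tpm else ta >= min_tpm | tb >= min_tpm
  tags[keep]
}

#' Tag abundance histogram
#'
#' Bins rounded tpm values into fixed-width bins (1-10, 11-20, ... for the
#' default width of 10); tags rounding below 1 tpm fall outside the plotted
#' range and are dropped. Also reports the fraction of binned tags below a
#' threshold, e.g. the share of the transcriptome expressed at under 20 tpm.
#'
#' @param table An `expression_table`.
#' @param bin_width Bin width in tpm, default 10.
#' @param low_threshold Threshold for the reported low-expression fraction.
#' @return List with `histogram` (data.frame: bin label, lower, upper, n),
#'   `fraction_below` and `threshold`.
#' @export
abundance_distribution <- function(table, bin_width = 10, low_threshold = 20) {
  if (bin_width <= 0) stop_config("bin_width must be positive")
  if (NROW(table) == 0L) stop_degenerate("empty expression table")
  r <- round_half_up(table$tpm)
  r <- r[r >= 1]
  if (length(r) == 0L) {
    hist <- data.frame(bin = character(0), lower = numeric(0),
                       upper = numeric(0), n = integer(0))
    return(list(histogram = hist, fraction_below = NA_real_,
                threshold = low_threshold))
  }
  idx <- ceiling(r / bin_width)
  tab <- table(idx)
  lower <- (as.integer(names(tab)) - 1L) * bin_width + 1
  upper <- as.integer(names(tab)) * bin_width
  hist <- data.frame(bin = sprintf("%d-%d", lower, upper),
                     lower = lower, upper = upper,
                     n = as.integer(tab), stringsAsFactors = FALSE)
  list(histogram = hist,
       fraction_below = mean(r < low_threshold),
       threshold = low_threshold)
}

#' Mean MPSS tags per gene
#'
#' Ratio of class 1-5 tags with a defined gene to the number of distinct
#' genes they cover, reported to two decimals. Values above 1 reflect genes
#' represented by several signatures, e.g. via alternative polyadenylation.
#'
#' @param mapped A [map_and_classify()] result (or any data.frame with
#'   tag, tag_class, gene_id).
#' @return List with `n_tags`, `n_genes` and `tags_per_gene` (2 dp).
#' @export
tags_per_gene <- function(mapped) {
  keep <- mapped$tag_class %in% c("1", "2", "3", "4", "5") & !is.na(mapped$gene_id)
  n_tags <- length(unique(mapped$tag[keep]))
  n_genes <- length(unique(mapped$gene_id[keep]))
  if (n_genes == 0L) stop_degenerate("no tags with a defined gene")
  list(n_tags = n_tags, n_genes = n_genes,
       tags_per_gene = round(n_tags / n_genes, 2))
}
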