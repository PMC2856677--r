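#' Simulation configuration for synthetic MPSS experiments
#'
#' Bundles every knob of the synthetic-data generator: transcriptome shape,
#' planted differential expression, and MPSS library sampling. Defaults mirror
#' a two-pool brain MPSS experiment: libraries of ~1.5 million tags, two
#' technical replicates in each of the 2-step and 3-step sequencing series,
#' and a heavy-tailed (log-normal) abundance law under which most tags sit
#' below 20 tpm.
#'
#' @param n_genes Number of genes to simulate.
#' @param isoform_prob Probability that a gene carries a second, shorter 3'
#'   isoform (alternative polyadenylation), giving it a second signature.
#' @param frac_de Fraction of genes with planted differential expression.
#' @param log2_fc_mean,log2_fc_sd Mean and sd of the planted |log2 fold
#'   change|; each DE gene's change gets a random sign.
#' @param library_size Expected tags per library (Poisson mean), default
#'   1,500,000.
#' @param n_replicates_per_stepper Technical replicates per stepper series
#'   per condition, default 2 (so 8 libraries in a two-condition design).
#' @param expression_meanlog,expression_sdlog Log-normal parameters of the
#'   per-gene abundance law (meanlog is immaterial after normalisation).
#' @param decoy_frac Fraction of each library drawn from unannotated decoy
#'   sequences (genomic background), default 0.05.
#' @param n_decoys Number of decoy sequences.
#' @param overdispersion Dirichlet-multinomial overdispersion; 0 (default)
#'   gives pure multinomial technical-replicate noise.
#' @param signature_length Signature length in bases including the leading
#'   GATC, default 21.
#' @param polya_min Minimum terminal A-run length recognised as poly(A).
#' @param len_range Transcript body length range (nt), default 500-3000.
#' @param conditions Labels of the two conditions; the first is the tumour
#'   (numerator) pool by convention.
#' @param seed Integer RNG seed; the same seed reproduces every downstream
#'   artefact byte for byte.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 1000L,
                       isoform_prob = 0.1,
                       frac_de = 0.1,
                       log2_fc_mean = 2,
                       log2_fc_sd = 0.5,
                       library_size = 1500000,
                       n_replicates_per_stepper = 2L,
                       expression_meanlog = 0,
                       expression_sdlog = 1.7,
                       decoy_frac = 0.05,
                       n_decoys = 50L,
                       overdispersion = 0,
                       signature_length = 21L,
                       polya_min = 15L,
                       len_range = c(500L, 3000L),
                       conditions = c("gbm", "normal"),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              isoform_prob = isoform_prob,
              frac_de = frac_de,
              log2_fc_mean = log2_fc_mean,
              log2_fc_sd = log2_fc_sd,
              library_size = library_size,
              n_replicates_per_stepper = as.integer(n_replicates_per_stepper),
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              decoy_frac = decoy_frac,
              n_decoys = as.integer(n_decoys),
              overdispersion = overdispersion,
              signature_length = as.integer(signature_length),
              polya_min = as.integer(polya_min),
              len_range = as.integer(len_range),
              conditions = as.character(conditions),
              seed = as.integer(seed))
  if (cfg$n_genes < 1L) stop_config("n_genes must be >= 1")
  if (cfg$isoform_prob < 0 || cfg$isoform_prob > 1)
    stop_config("isoform_prob must be in [0,1]")
  if (cfg$frac_de < 0 || cfg$frac_de > 1) stop_config("frac_de must be in [0,1]")
  if (cfg$library_size <= 0) stop_config("library_size must be > 0")
  if (cfg$n_replicates_per_stepper < 1L)
    stop_config("n_replicates_per_stepper must be >= 1")
  if (cfg$decoy_frac < 0 || cfg$decoy_frac >= 1)
    stop_config("decoy_frac must be in [0,1)")
  if (cfg$decoy_frac > 0 && cfg$n_decoys < 1L)
    stop_config("decoy_frac > 0 requires n_decoys >= 1")
  if (cfg$signature_length < 8L) stop_config("signature_length must be >= 8")
  if (length(cfg$len_range) != 2L || cfg$len_range[1] > cfg$len_range[2] ||
      cfg$len_range[1] < cfg$signature_length + 120L)
    stop_config("len_range must be an increasing pair well above signature_length")
  if (length(cfg$conditions) != 2L || anyDuplicated(cfg$conditions))
    stop_config("conditions must be two distinct labels")
  if (is.na(cfg$seed)) stop_config("seed must be a finite integer")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic transcriptome with decoy background
#'
#' Each gene gets a transcript body of random sequence with one guaranteed
#' DpnII (GATC) site placed so that a full signature fits upstream of the
#' terminal poly(A) run; a fraction of genes gains a second, truncated 3'
#' isoform with its own signature (alternative polyadenylation). Decoys are
#' poly(A)-free random sequences standing in for unannotated genomic
#' background.
#'
#' @param config A [sim_config()].
#' @return An object of class `mpss_transcriptome`: a list with
#'   `transcripts` (data.frame: transcript_id, gene_id, sequence, length,
#'   polya_start, strand) and `decoys` (data.frame: decoy_id, sequence).
#'   `polya_start` is the 1-based position at which the poly(A) run starts,
#'   i.e. the annotated 3' end is `polya_start - 1`.
#' @export
generate_transcriptome <- function(config) {
  if (!inherits(config, "sim_config")) stop_config("config must be a sim_config")
  set.seed(config$seed)
  sl <- config$signature_length
  n <- config$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))

  body_len <- sample(config$len_range[1]:config$len_range[2], n, replace = TRUE)
  bodies <- random_dna(body_len)
  # terminal base forced non-A so the poly(A) run is exactly the appended tail
  substr(bodies, body_len, body_len) <- "C"
  pos <- 1L + floor(stats::runif(n) * (body_len - sl + 1L))
  substr(bodies, pos, pos + 3L) <- "GATC"

  polya_len <- config$polya_min + stats::rpois(n, 5)
  second <- stats::runif(n) < config$isoform_prob

  tx <- data.frame(transcript_id = paste0(gene_id, ".1"),
                   gene_id = gene_id,
                   sequence = paste0(bodies, strrep("A", polya_len)),
                   length = body_len + polya_len,
                   polya_start = body_len + 1L,
                   strand = "+",
                   stringsAsFactors = FALSE)

  if (any(second)) {
    idx <- which(second)
    lo <- sl + 60L
    cut <- lo + floor(stats::runif(length(idx)) * (body_len[idx] - 120L - lo + 1L))
    b2 <- substr(bodies[idx], 1L, cut)
    substr(b2, cut, cut) <- "C"
    pos2 <- 1L + floor(stats::runif(length(idx)) * (cut - sl + 1L))
    substr(b2, pos2, pos2 + 3L) <- "GATC"
    pa2 <- config$polya_min + stats::rpois(length(idx), 5)
    iso <- data.frame(transcript_id = paste0(gene_id[idx], ".2"),
                      gene_id = gene_id[idx],
                      sequence = paste0(b2, strrep("A", pa2)),
                      length = cut + pa2,
                      polya_start = cut + 1L,
                      strand = "+",
                      stringsAsFactors = FALSE)
    tx <- rbind(tx, iso)
    tx <- tx[order(tx$transcript_id), , drop = FALSE]
    rownames(tx) <- NULL
  }

  decoys <- data.frame(decoy_id = character(0), sequence = character(0),
                       stringsAsFactors = FALSE)
  if (config$n_decoys > 0L) {
    dlen <- rep(1000L, config$n_decoys)
    dseq <- random_dna(dlen)
    substr(dseq, dlen, dlen) <- "C"
    dpos <- 1L + floor(stats::runif(config$n_decoys) * (dlen - sl + 1L))
    substr(dseq, dpos, dpos + 3L) <- "GATC"
    decoys <- data.frame(decoy_id = sprintf("D%04d", seq_len(config$n_decoys)),
                         sequence = dseq, stringsAsFactors = FALSE)
  }

  structure(list(transcripts = tx, decoys = decoys,
                 signature_length = sl, polya_min = config$polya_min),
            class = "mpss_transcriptome")
}

#' @export
print.mpss_transcriptome <- function(x, ...) {
  cat(sprintf("mpss_transcriptome: %d transcripts / %d genes, %d decoys\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id)),
              nrow(x$decoys)))
  invisible(x)
}

#' Simulate true expression with planted differential expression
#'
#' Gene abundances in condition A are drawn from a log-normal law and split
#' across a gene's isoforms; a fraction `frac_de` of genes gets its condition
#' B abundance multiplied by `2^fc` with `fc ~ Normal(log2_fc_mean,
#' log2_fc_sd)` under a random sign, after which each condition is
#' renormalised to sum to one over all transcripts plus decoys. Decoys hold a
#' fixed `decoy_frac` share of both conditions.
#'
#' @param transcriptome An [generate_transcriptome()] result.
#' @param config The same [sim_config()].
#' @return An object of class `mpss_ground_truth`: data.frame with columns
#'   id, gene_id (NA for decoys), type ("transcript"/"decoy"), abund_a,
#'   abund_b, is_de, log2_fc. Condition A is `config$conditions[2]` (the
#'   baseline/normal pool) and B is `config$conditions[1]` (tumour).
#' @export
simulate_expression <- function(transcriptome, config) {
  if (!inherits(transcriptome, "mpss_transcriptome"))
    stop_input("transcriptome must come from generate_transcriptome()")
  if (!inherits(config, "sim_config")) stop_config("config must be a sim_config")
  set.seed(config$seed + 1L)

  tx <- transcriptome$transcripts
  genes <- unique(tx$gene_id)
  n <- length(genes)
  g_ab <- stats::rlnorm(n, config$expression_meanlog, config$expression_sdlog)
  names(g_ab) <- genes

  # split a gene's abundance across its isoforms (uniform random weights)
  w <- stats::runif(nrow(tx), min = 0.2, max = 1)
  wsum <- tapply(w, tx$gene_id, sum)
  tx_ab <- g_ab[tx$gene_id] * w / as.numeric(wsum[tx$gene_id])

  n_de <- round(config$frac_de * n)
  de_genes <- if (n_de > 0L) sample(genes, n_de) else character(0)
  fc <- numeric(n)
  names(fc) <- genes
  if (n_de > 0L) {
    mag <- stats::rnorm(n_de, config$log2_fc_mean, config$log2_fc_sd)
    fc[de_genes] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
  }
  tx_mult <- 2^fc[tx$gene_id]

  tr_share <- 1 - config$decoy_frac
  abund_a <- tx_ab / sum(tx_ab) * tr_share
  ab_b_raw <- abund_a * tx_mult
  abund_b <- ab_b_raw / sum(ab_b_raw) * tr_share

  truth <- data.frame(id = tx$transcript_id,
                      gene_id = tx$gene_id,
                      type = "transcript",
                      abund_a = abund_a,
                      abund_b = abund_b,
                      is_de = tx$gene_id %in% de_genes,
                      log2_fc = fc[tx$gene_id],
                      stringsAsFactors = FALSE)

  if (nrow(transcriptome$decoys) > 0L && config$decoy_frac > 0) {
    d_ab <- stats::rlnorm(nrow(transcriptome$decoys), 0, 1)
    d_ab <- d_ab / sum(d_ab) * config$decoy_frac
    truth <- rbind(truth,
                   data.frame(id = transcriptome$decoys$decoy_id,
                              gene_id = NA_character_,
                              type = "decoy",
                              abund_a = d_ab, abund_b = d_ab,
                              is_de = FALSE, log2_fc = 0,
                              stringsAsFactors = FALSE))
  }
  rownames(truth) <- NULL
  structure(truth, class = c("mpss_ground_truth", "data.frame"))
}

#' Simulate MPSS tag-count libraries with technical replicates
#'
#' For each condition, each stepper series (2-step, 3-step) and each
#' replicate, the library total is drawn Poisson around the configured size
#' and tags are sampled multinomially with per-source probability
#' proportional to true abundance; each source contributes its 3'-most DpnII
#' signature (via [extract_signature()]). Steppers are exchangeable replicate
#' groups: no base-calling error model is applied. With `overdispersion > 0`
#' the per-library probabilities are jittered Dirichlet-style to emulate
#' extra-multinomial technical noise.
#'
#' @param transcriptome,truth,config The generator triple.
#' @return A list of [tag_library()] objects (2 conditions x 2 steppers x
#'   `n_replicates_per_stepper`).
#' @export
simulate_mpss_libraries <- function(transcriptome, truth, config) {
  # validate (and thereby force) all arguments before touching the RNG
  if (!inherits(transcriptome, "mpss_transcriptome"))
    stop_input("transcriptome must come from generate_transcriptome()")
  if (!inherits(truth, "mpss_ground_truth"))
    stop_input("truth must come from simulate_expression()")
  if (!inherits(config, "sim_config")) stop_config("config must be a sim_config")
  set.seed(config$seed + 2L)

  src <- source_signatures(transcriptome)
  tag_of <- src$tag[match(truth$id, src$id)]
  keep <- !is.na(tag_of)
  if (!any(keep)) stop_degenerate("no source sequence yields an extractable signature")

  prob_tab <- function(ab) {
    p <- ab[keep] / sum(ab[keep])
    rowsum(p, tag_of[keep])
  }
  pa <- prob_tab(truth$abund_a)
  pb <- prob_tab(truth$abund_b)
  tags <- rownames(pa)

  cond_prob <- list(pa[, 1L], pb[, 1L])
  # conditions[1] is the tumour pool = condition B of the truth table
  names(cond_prob) <- c(config$conditions[2L], config$conditions[1L])

  libs <- list()
  for (cond in config$conditions) {
    p0 <- cond_prob[[cond]]
    for (stepper in c("2-step", "3-step")) {
      for (r in seq_len(config$n_replicates_per_stepper)) {
        p <- p0
        if (config$overdispersion > 0) {
          g <- stats::rgamma(length(p0), shape = p0 / config$overdispersion)
          if (sum(g) > 0) p <- g / sum(g)
        }
        total <- stats::rpois(1L, config$library_size)
        cnt <- stats::rmultinom(1L, total, p)[, 1L]
        names(cnt) <- tags
        cnt <- cnt[cnt > 0L]
        id <- sprintf("%s_%s_r%d", cond, stepper, r)
        libs[[id]] <- tag_library(id, cond, stepper, r, cnt, total)
      }
    }
  }
  libs
}

# 3'-most signature of every annotated transcript and decoy; internal.
source_signatures <- function(transcriptome) {
  tx <- transcriptome$transcripts
  sl <- transcriptome$signature_length
  pm <- transcriptome$polya_min
  ids <- c(tx$transcript_id, transcriptome$decoys$decoy_id)
  seqs <- c(tx$sequence, transcriptome$decoys$sequence)
  data.frame(id = ids,
             tag = extract_signature(seqs, sl, pm),
             stringsAsFactors = FALSE)
}

#' True per-tag differential-expression status
#'
#' Collapses the transcript-level ground truth to the tag level: a tag is
#' truly differentially expressed if any transcript emitting it belongs to a
#' DE gene. Used to score realised false-discovery proportions in
#' simulations.
#'
#' @param transcriptome,truth The generator pair.
#' @return data.frame(tag, is_de, gene_id of the first contributing source).
#' @export
true_tag_status <- function(transcriptome, truth) {
  src <- source_signatures(transcriptome)
  m <- merge(src, truth, by = "id")
  m <- m[!is.na(m$tag), , drop = FALSE]
  de <- tapply(m$is_de, m$tag, any)
  gene <- tapply(m$gene_id, m$tag, function(g) g[1L])
  data.frame(tag = names(de), is_de = as.logical(de),
             gene_id = as.character(gene), stringsAsFactors = FALSE)
}
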