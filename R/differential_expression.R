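#' Two-library proportion Z-test for tag counts
#'
#' The pooled two-proportion statistic used for SAGE/MPSS library
#' comparisons: with `p1 = x1/n1`, `p2 = x2/n2` and pooled
#' `p0 = (x1+x2)/(n1+n2)`,
#' `z = (p1 - p2) / sqrt(p0 (1 - p0) (1/n1 + 1/n2))`,
#' with a two-sided normal p-value. Degenerate pooled proportions (0 or 1)
#' give `z = 0, p = 1`. Vectorised over all four arguments.
#'
#' @param x1,x2 Tag counts in the two libraries.
#' @param n1,n2 Library totals (must be positive).
#' @param tag Optional tag identifiers carried through to the result.
#' @return data.frame(tag?, x1, n1, x2, n2, z, p).
#' @export
ztest <- function(x1, n1, x2, n2, tag = NULL) {
  if (any(n1 <= 0) || any(n2 <= 0)) stop_input("library totals must be positive")
  if (any(x1 < 0) || any(x2 < 0) || any(x1 > n1) || any(x2 > n2))
    stop_input("counts must satisfy 0 <= x <= n")
  p0 <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p0 * (1 - p0) * (1 / n1 + 1 / n2))
  z <- ifelse(p0 <= 0 | p0 >= 1, 0, (x1 / n1 - x2 / n2) / se)
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(x1 = x1, n1 = n1, x2 = x2, n2 = n2, z = z, p = p)
  if (!is.null(tag)) out <- cbind(tag = tag, out, stringsAsFactors = FALSE)
  out
}

#' Build the empirical null distribution from technical replicates
#'
#' Steps 1-3 of the empirical-null FDR procedure: within each condition,
#' technical replicates are compared pairwise with [ztest()] (replicates are
#' paired within a stepper series; a leftover single replicate per stepper
#' is paired across series), each comparison's p-value is transformed back
#' to a Z value via the upper-tail standard-normal quantile, and the Z
#' values from all within-condition comparisons are pooled. Since the
#' quantile transform of a signed z statistic's upper-tail p recovers that
#' statistic exactly, the pooled null is the multiset of signed
#' within-condition z values. Each pair contributes its union of observed
#' (nonzero) tags.
#'
#' @param libraries List of [tag_library()] objects covering both
#'   conditions, each with at least two technical replicates.
#' @return An object of class `empirical_null`: list with `z` (pooled null
#'   values), `source` (condition/pair label per value) and
#'   `n_comparisons`.
#' @export
build_empirical_null <- function(libraries) {
  conds <- vapply(libraries, function(l) l$condition, "")
  pairs <- list()
  for (cond in unique(conds)) {
    libs <- libraries[conds == cond]
    if (length(libs) < 2L)
      stop_input(sprintf("condition '%s' has fewer than 2 technical replicates", cond))
    ord <- order(vapply(libs, function(l) l$stepper, ""),
                 vapply(libs, function(l) l$replicate, 0L))
    libs <- libs[ord]
    leftovers <- list()
    for (st in unique(vapply(libs, function(l) l$stepper, ""))) {
      grp <- libs[vapply(libs, function(l) l$stepper, "") == st]
      while (length(grp) >= 2L) {
        pairs[[length(pairs) + 1L]] <- list(a = grp[[1L]], b = grp[[2L]], cond = cond)
        grp <- grp[-(1:2)]
      }
      leftovers <- c(leftovers, grp)
    }
    while (length(leftovers) >= 2L) {
      pairs[[length(pairs) + 1L]] <- list(a = leftovers[[1L]], b = leftovers[[2L]],
                                          cond = cond)
      leftovers <- leftovers[-(1:2)]
    }
    if (!any(vapply(pairs, function(p) p$cond == cond, TRUE)))
      stop_input(sprintf("condition '%s' yields no replicate pair", cond))
  }

  z <- numeric(0)
  src <- character(0)
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    tags <- sort(unique(c(names(pr$a$counts), names(pr$b$counts))))
    xa <- pr$a$counts[tags]; xa[is.na(xa)] <- 0
    xb <- pr$b$counts[tags]; xb[is.na(xb)] <- 0
    zz <- ztest(as.numeric(xa), pr$a$total_tags,
                as.numeric(xb), pr$b$total_tags)$z
    z <- c(z, zz)
    src <- c(src, rep(sprintf("%s:%s|%s", pr$cond, pr$a$library_id,
                              pr$b$library_id), length(zz)))
  }
  structure(list(z = z, source = src, n_comparisons = length(pairs)),
            class = "empirical_null")
}

#' @export
print.empirical_null <- function(x, ...) {
  cat(sprintf("empirical_null: %d Z values from %d within-condition comparisons\n",
              length(x$z), x$n_comparisons))
  invisible(x)
}

#' Estimate the true-null proportion (Storey-type)
#'
#' `pi0 = min(1, 2 * #{p > 0.5} / m)`: p-values above 0.5 are assumed to be
#' null-dominated and their doubled share estimates the fraction of
#' true-null tags.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return `pi0` in \[0, 1\].
#' @export
estimate_pi0 <- function(p_values) {
  if (length(p_values) == 0L) stop_degenerate("no p-values supplied")
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop_input("p-values must lie in [0, 1]")
  min(1, 2 * sum(p_values > 0.5) / length(p_values))
}

#' Empirical-null FDR for observed tag comparisons
#'
#' Steps 4-6 of the procedure. The observed Z values come from [ztest()]
#' applied to the replicate-mean counts and totals of the two conditions
#' (rounded to integers by the caller, see [mpss_de()]). For each tag the
#' empirical tail probability is the fraction of null values at least as
#' extreme, with a plus-one correction to avoid zeros:
#' `p_emp = (1 + #extreme null) / (N_null + 1)`. Two modes:
#'
#' * `"storey"` (default) — the tail-ratio q-value form
#'   `fdr = pi0 * p_emp * m / #{ |z_j| >= |z_i| }`, i.e. expected false
#'   positives over observed discoveries at each threshold;
#' * `"literal"` — `fdr = pi0 * p_emp`, the procedure exactly as stated in
#'   its source description (anti-conservative: it omits division by the
#'   observed discovery fraction; retained for fidelity).
#'
#' Both are clipped to \[0, 1\] and smoothed so that fdr is nondecreasing in
#' `p_emp` (running minimum from the least significant tag downwards, as for
#' q-values). Sidedness: `"two"` compares `|Z|` (the default; the analysis
#' reports both up- and down-regulated tags), `"one"` uses the upper tail
#' `Z >= z_i` as literally stated.
#'
#' @param observed A [ztest()] result with a `tag` column (one row per tag).
#' @param null An [build_empirical_null()] result.
#' @param mode "storey" or "literal".
#' @param sided "two" or "one".
#' @param pi0 Optional; defaults to [estimate_pi0()] of the observed
#'   p-values.
#' @param cutoff FDR call threshold (strict `<`), default 0.1.
#' @return An `fdr_result` data.frame: tag, x1, n1, x2, n2, z, p, p_emp,
#'   pi0, fdr, called; ordered by increasing p_emp with ties broken by tag.
#' @export
compute_fdr <- function(observed, null, mode = c("storey", "literal"),
                        sided = c("two", "one"), pi0 = NULL, cutoff = 0.1) {
  mode <- match.arg(mode)
  sided <- match.arg(sided)
  if (NROW(observed) == 0L) stop_degenerate("no observed results")
  if (!inherits(null, "empirical_null") || length(null$z) == 0L)
    stop_input("null must be a nonempty empirical_null")
  if (is.null(observed$tag)) stop_input("observed must carry a tag column")

  z <- observed$z
  m <- length(z)
  nn <- length(null$z)
  if (sided == "two") {
    sn <- sort(abs(null$z))
    n_extreme <- nn - findInterval(abs(z), sn, left.open = TRUE)
    so <- sort(abs(z))
    n_disc <- m - findInterval(abs(z), so, left.open = TRUE)
  } else {
    sn <- sort(null$z)
    n_extreme <- nn - findInterval(z, sn, left.open = TRUE)
    so <- sort(z)
    n_disc <- m - findInterval(z, so, left.open = TRUE)
  }
  p_emp <- (1 + n_extreme) / (nn + 1)
  pi0 <- pi0 %||% estimate_pi0(observed$p)
  pi0 <- min(1, max(0, pi0))

  fdr <- switch(mode,
                storey = pmin(1, pi0 * p_emp * m / n_disc),
                literal = pmin(1, pi0 * p_emp))

  out <- observed
  out$p_emp <- p_emp
  out$pi0 <- pi0
  out$fdr <- fdr

  # deterministic order: increasing significance ties broken by tag id
  ord <- order(out$p_emp, out$tag)
  out <- out[ord, , drop = FALSE]
  # step-up smoothing: fdr nondecreasing in p_emp
  out$fdr <- rev(cummin(rev(out$fdr)))
  out$called <- out$fdr < cutoff
  rownames(out) <- NULL
  class(out) <- c("fdr_result", "data.frame")
  attr(out, "cutoff") <- cutoff
  attr(out, "mode") <- mode
  out
}

#' Select differentially expressed tags
#'
#' Tags with `fdr < cutoff` (strict inequality; a tag at exactly the cutoff
#' is not called).
#'
#' @param fdr_result A [compute_fdr()] result.
#' @param cutoff FDR threshold in (0, 1), default 0.1.
#' @return Character vector of called tag sequences.
#' @export
call_degs <- function(fdr_result, cutoff = 0.1) {
  if (cutoff <= 0 || cutoff >= 1) stop_config("cutoff must be in (0, 1)")
  if (NROW(fdr_result) == 0L) return(character(0))
  fdr_result$tag[fdr_result$fdr < cutoff]
}

#' Roll tag-level calls up to genes
#'
#' A gene is differentially expressed as soon as one of its tags is called
#' (different tags may represent different isoforms of the gene). Direction
#' is the sign of z of the gene's most significant called tag; a gene with
#' called tags of both signs is reported as `conflict` and excluded from the
#' up/down totals.
#'
#' @param fdr_result A [compute_fdr()] result (rows ordered or not).
#' @param tag2gene data.frame(tag, gene_id) mapping; tags without a gene
#'   (NA) are dropped from the rollup.
#' @param cutoff FDR threshold, default the one stored in `fdr_result`.
#' @return A `gene_call` data.frame: gene_id, n_tags, n_called, gene_de,
#'   direction ("up", "down", "conflict", "none"), min_fdr; sorted by
#'   gene_id.
#' @export
rollup_genes <- function(fdr_result, tag2gene, cutoff = NULL) {
  cutoff <- cutoff %||% attr(fdr_result, "cutoff") %||% 0.1
  m <- merge(fdr_result, tag2gene, by = "tag")
  m <- m[!is.na(m$gene_id), , drop = FALSE]
  if (nrow(m) == 0L)
    return(structure(data.frame(gene_id = character(0), n_tags = integer(0),
                                n_called = integer(0), gene_de = logical(0),
                                direction = character(0), min_fdr = numeric(0)),
                     class = c("gene_call", "data.frame")))
  m$called <- m$fdr < cutoff
  # most significant first; ties by tag for determinism
  m <- m[order(m$gene_id, m$fdr, m$p, m$tag), , drop = FALSE]
  sp <- split(m, m$gene_id)
  out <- do.call(rbind, lapply(sp, function(g) {
    called <- g[g$called, , drop = FALSE]
    dir <- if (nrow(called) == 0L) "none"
    else {
      signs <- unique(sign(called$z[called$z != 0]))
      if (length(signs) > 1L) "conflict"
      else if (called$z[1L] > 0) "up"
      else if (called$z[1L] < 0) "down"
      else "none"
    }
    data.frame(gene_id = g$gene_id[1L], n_tags = nrow(g),
               n_called = nrow(called), gene_de = nrow(called) > 0L,
               direction = dir, min_fdr = min(g$fdr),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_call", "data.frame")
  out
}

#' Run the full two-condition differential-expression procedure
#'
#' Convenience wrapper tying the six steps together for a set of replicate
#' libraries: merge steppers per condition, filter to expressed tags,
#' Z-test the rounded replicate-mean counts against the rounded mean
#' totals, build the empirical null from within-condition replicate pairs,
#' convert to empirical-null FDR and call tags.
#'
#' @param libraries List of [tag_library()] objects for both conditions.
#' @param conditions Length-2 character: the comparison is
#'   `conditions[1] - conditions[2]` (positive z = higher in the first,
#'   tumour, condition). Default: order of first appearance.
#' @param min_tpm,strict Expression filter, see [filter_expressed()];
#'   `filter = FALSE` tests every observed tag.
#' @param cutoff,mode,sided FDR parameters, see [compute_fdr()].
#' @param filter Apply the expression filter (default TRUE).
#' @return List of class `mpss_de_result`: `expression` (per-condition
#'   tables), `observed`, `null`, `fdr` (fdr_result), `called`,
#'   `conditions`.
#' @export
mpss_de <- function(libraries, conditions = NULL, min_tpm = 3, strict = TRUE,
                    filter = TRUE, cutoff = 0.1, mode = "storey",
                    sided = "two") {
  conds_all <- vapply(libraries, function(l) l$condition, "")
  conditions <- conditions %||% unique(conds_all)
  if (length(conditions) != 2L || !all(conditions %in% conds_all))
    stop_input("need libraries from exactly the two requested conditions")

  e1 <- merge_steppers(libraries[conds_all == conditions[1L]])
  e2 <- merge_steppers(libraries[conds_all == conditions[2L]])
  tags <- if (filter) filter_expressed(e1, e2, min_tpm, strict)
          else sort(unique(c(e1$tag, e2$tag)))
  if (length(tags) == 0L) stop_degenerate("no tags pass the expression filter")

  stat_for <- function(e, libs) {
    i <- match(tags, e$tag)
    cnt <- e$count[i]
    cnt[is.na(cnt)] <- 0
    tot <- e$total[i]
    # a tag unseen in this condition gets the tie-rule stepper's mean total
    fallback <- mean(vapply(libs[vapply(libs, function(l) l$stepper, "") == "2-step"],
                            function(l) l$total_tags, 0))
    if (is.nan(fallback))
      fallback <- mean(vapply(libs, function(l) l$total_tags, 0))
    tot[is.na(tot)] <- fallback
    list(x = round_half_up(cnt), n = round_half_up(tot))
  }
  s1 <- stat_for(e1, libraries[conds_all == conditions[1L]])
  s2 <- stat_for(e2, libraries[conds_all == conditions[2L]])

  observed <- ztest(s1$x, s1$n, s2$x, s2$n, tag = tags)
  null <- build_empirical_null(libraries)
  fdr <- compute_fdr(observed, null, mode = mode, sided = sided, cutoff = cutoff)
  expr <- list(e1, e2)
  names(expr) <- conditions
  structure(list(expression = expr, observed = observed, null = null,
                 fdr = fdr, called = call_degs(fdr, cutoff),
                 conditions = conditions),
            class = "mpss_de_result")
}

#' @export
print.mpss_de_result <- function(x, ...) {
  cat(sprintf("mpss_de_result: %s vs %s, %d tags tested, %d called (pi0=%.3f)\n",
              x$conditions[1L], x$conditions[2L], nrow(x$fdr),
              length(x$called), x$fdr$pi0[1L]))
  invisible(x)
}

#' Run one synthetic two-condition experiment end to end
#'
#' Generates a transcriptome, plants expression, simulates replicate MPSS
#' libraries, runs [mpss_de()] and scores the calls against the known
#' truth. The realised false-discovery proportion counts every called tag
#' that does not descend from a DE gene as a false positive.
#'
#' @param config A [sim_config()].
#' @param min_tpm,cutoff,mode Passed to [mpss_de()].
#' @return List: `de` (the [mpss_de()] result), `truth` (per-tag truth),
#'   `fdp`, `n_called`, `sensitivity` (among tested truly-DE tags).
#' @export
simulate_de_experiment <- function(config, min_tpm = 3, cutoff = 0.1,
                                   mode = "storey") {
  tx <- generate_transcriptome(config)
  truth <- simulate_expression(tx, config)
  libs <- simulate_mpss_libraries(tx, truth, config)
  de <- mpss_de(libs, conditions = config$conditions, min_tpm = min_tpm,
                cutoff = cutoff, mode = mode)
  tt <- true_tag_status(tx, truth)
  called_true <- tt$is_de[match(de$called, tt$tag)]
  tested_de <- de$fdr$tag %in% tt$tag[tt$is_de]
  list(de = de, truth = tt,
       fdp = if (length(de$called)) mean(!(called_true %in% TRUE)) else 0,
       n_called = length(de$called),
       sensitivity = if (any(tested_de))
         sum(de$fdr$called & tested_de) / sum(tested_de) else NA_real_)
}
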