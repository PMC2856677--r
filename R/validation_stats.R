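#' Fisher's exact test for a 2x2 contingency table
#'
#' Exact two-sided p-value under the probability-mass criterion: with
#' margins fixed, it sums the hypergeometric probabilities of every table
#' whose probability does not exceed that of the observed table (within a
#' relative tie tolerance of 1e-12). This is the convention under which the
#' test is usually reported for immunostaining summaries; other two-sided
#' conventions (doubling the smaller tail) exist and give different values.
#'
#' @param table 2x2 matrix of nonnegative integer counts; rows are groups
#'   (e.g. Normal, Glioblastoma), columns outcomes (Negative, Positive).
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L))) stop_input("table must be 2x2")
  if (any(tb < 0) || any(tb != round(tb)))
    stop_input("cells must be nonnegative integers")
  if (sum(tb) == 0) stop_input("table has no observations")
  r1 <- sum(tb[1L, ]); r2 <- sum(tb[2L, ]); c1 <- sum(tb[, 1L])
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, r2, c1)
  p_obs <- stats::dhyper(tb[1L, 1L], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Positive rate of a group in a 2x2 staining table
#'
#' `100 * positives / (negatives + positives)` for one group row, rounded
#' to an integer percentage as such tables are conventionally printed.
#'
#' @param table 2x2 matrix with columns (Negative, Positive); rows may be
#'   named.
#' @param group Row index or row name.
#' @return Integer percentage.
#' @export
positive_rate <- function(table, group) {
  tb <- as.matrix(table)
  row <- tb[group, ]
  if (sum(row) == 0) stop_input("group row has zero total")
  as.integer(round_half_up(100 * row[2L] / sum(row)))
}

#' Welch two-sample t-test
#'
#' Two-tailed t-test with unequal variances (Welch-Satterthwaite degrees of
#' freedom), as used to compare qPCR relative-expression levels between
#' tumour and normal panels. Thin wrapper over [stats::t.test()].
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop_input("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop_input("both groups have zero variance")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Comparative-Ct relative expression
#'
#' Per sample, `delta_Ct = mean(target Ct) - mean(control Ct)` over
#' replicate wells (the control being an endogenous reference such as GUS),
#' and the relative level is `2^(-delta_Ct)`. The standard error of
#' `delta_Ct` is propagated from the replicate variances
#' (`sqrt(var_t/n_t + var_c/n_c)`). An optional calibrator sample rescales
#' all levels by its own (the delta-delta-Ct form).
#'
#' @param ct data.frame with columns sample_id, group, target_ct,
#'   control_ct (one row per replicate well).
#' @param calibrator Optional sample_id used as the delta-delta-Ct
#'   reference.
#' @return data.frame(sample_id, group, n_target, n_control, delta_ct,
#'   se_delta_ct, relative_level), sorted by sample_id.
#' @export
relative_expression <- function(ct, calibrator = NULL) {
  need <- c("sample_id", "group", "target_ct", "control_ct")
  if (!all(need %in% names(ct))) stop_input("ct needs columns ",
                                            paste(need, collapse = ", "))
  if (any(!is.finite(ct$target_ct)) || any(!is.finite(ct$control_ct)))
    stop_input("Ct values must be finite")
  sp <- split(ct, ct$sample_id)
  out <- do.call(rbind, lapply(sp, function(s) {
    nt <- sum(!is.na(s$target_ct))
    nc <- sum(!is.na(s$control_ct))
    dct <- mean(s$target_ct) - mean(s$control_ct)
    vt <- if (nt > 1L) stats::var(s$target_ct) else 0
    vc <- if (nc > 1L) stats::var(s$control_ct) else 0
    data.frame(sample_id = s$sample_id[1L], group = s$group[1L],
               n_target = nt, n_control = nc,
               delta_ct = dct,
               se_delta_ct = sqrt(vt / nt + vc / nc),
               relative_level = 2^(-dct),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(calibrator)) {
    i <- match(calibrator, out$sample_id)
    if (is.na(i)) stop_input("calibrator sample not found")
    out$relative_level <- out$relative_level / out$relative_level[i]
  }
  out
}
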