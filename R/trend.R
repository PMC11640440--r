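# Longitudinal trend analysis: pair pre/post feature tables per patient,
# compute absolute and relative deviations with the zero/absence edge rules,
# and evaluate cohort-level dynamics with macro-averaged relative differences
# and dependent paired t-tests.
#
# Conventions:
#   * differences are post - pre, so treatment-induced decreases are negative;
#   * the relative-difference denominator is the pre (baseline) value;
#   * a feature absent in one condition is excluded at pairing; a zero
#     measurement in either condition sets the relative difference to exactly
#     0 (it still participates in the macro-average);
#   * the paired t-test runs on the raw extracted feature scores, two-sided.

#' Pair pre/post features for one patient
#'
#' Inner join of the two tables on (structure, metric). Features present in
#' only one condition are dropped — the pairwise-existence rule — and
#' reported via the `"dropped"` attribute.
#'
#' @param pre_table,post_table Feature data.frames for one patient (columns
#'   `patient_id`, `condition`, `structure`, `metric`, `value`).
#' @return A data.frame with columns `patient_id`, `structure`, `metric`,
#'   `pre`, `post`; attribute `dropped` lists excluded feature ids.
#' @export
pair_features <- function(pre_table, post_table) {
  pid <- unique(c(pre_table$patient_id, post_table$patient_id))
  if (length(pid) > 1L) {
    stop("pre and post tables belong to different patients: ",
         paste(pid, collapse = " vs "), call. = FALSE)
  }
  if (length(pid) == 0L) pid <- NA_character_
  key_pre <- paste(pre_table$structure, pre_table$metric, sep = ":")
  key_post <- paste(post_table$structure, post_table$metric, sep = ":")
  if (anyDuplicated(key_pre) || anyDuplicated(key_post)) {
    stop("duplicate (structure, metric) keys within a feature table",
         call. = FALSE)
  }
  common <- intersect(key_pre, key_post)
  dropped <- c(setdiff(key_pre, key_post), setdiff(key_post, key_pre))
  ip <- match(common, key_pre)
  iq <- match(common, key_post)
  out <- data.frame(
    patient_id = rep(pid, length(common)),
    structure = pre_table$structure[ip],
    metric = pre_table$metric[ip],
    pre = pre_table$value[ip],
    post = post_table$value[iq],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$structure, out$metric), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- sort(dropped)
  out
}

#' Absolute difference (post minus pre)
#'
#' @param pre_value,post_value Feature values in native units.
#' @return `post_value - pre_value`; negative means a decrease.
#' @export
absolute_difference <- function(pre_value, post_value) {
  post_value - pre_value
}

#' Relative difference in percent, with the zero rule
#'
#' `100 * (post - pre) / pre` when both values are nonzero; exactly 0 when
#' either value is zero. A zero measurement typically means a structure
#' collapsed to nothing (or appeared from nothing), where a percent change
#' from baseline is undefined or infinite; setting it to zero keeps the
#' record in the cohort average without letting it explode.
#'
#' @param pre_value,post_value Feature values in native units.
#' @return Relative difference in percent (vectorised).
#' @export
#' @examples
#' relative_difference_pct(100, 80)  # -20
#' relative_difference_pct(0, 5)     # 0 (zero rule)
relative_difference_pct <- function(pre_value, post_value) {
  ifelse(pre_value == 0 | post_value == 0, 0,
         100 * (post_value - pre_value) / pre_value)
}

#' Per-patient deviation records
#'
#' Adds absolute and relative differences plus a `flags` column to a paired
#' feature table. Rows hit by the zero rule are flagged `"zero_rule"`.
#'
#' @param paired Output of [pair_features()] (or several rbind-ed together).
#' @return The input with columns `abs_diff`, `rel_diff_pct`, `flags`.
#' @export
compute_deviations <- function(paired) {
  stopifnot(all(c("pre", "post") %in% names(paired)))
  paired$abs_diff <- absolute_difference(paired$pre, paired$post)
  paired$rel_diff_pct <- relative_difference_pct(paired$pre, paired$post)
  paired$flags <- ifelse(paired$pre == 0 | paired$post == 0, "zero_rule", "")
  paired
}

#' Macro-average of relative differences
#'
#' Arithmetic mean over the included per-patient relative differences for one
#' feature; every patient weighs equally. Values set to 0 by the zero rule
#' participate; excluded (absent) entries never reach this function.
#'
#' @param values Numeric vector of per-patient relative differences (%).
#' @return The mean, or `NA_real_` for an empty vector (feature skipped).
#' @export
macro_average <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    return(NA_real_)
  }
  mean(values)
}

#' Dependent t-test for paired samples
#'
#' Classical paired t on the differences `d = post - pre`: `t = mean(d) *
#' sqrt(n) / sd(d)` with `df = n - 1` and a two-sided p-value. Degenerate
#' cases follow fixed rules rather than erroring so cohort evaluation always
#' produces a row:
#' \itemize{
#'   \item `n < 2`: `t = 0`, `p = 1`, flag `"insufficient_n"`;
#'   \item zero-variance differences with nonzero mean: `p = 0`, `t`
#'     infinite with the sign of the mean, flag `"degenerate"`;
#'   \item zero-variance, zero-mean differences: `t = 0`, `p = 1`.
#' }
#'
#' @param pre_vec,post_vec Equal-length numeric vectors, aligned by patient.
#' @return A list with elements `t`, `df`, `p`, `flag` (`""` when regular).
#' @export
#' @examples
#' paired_t_test(c(0, 0, 0), c(1, 1, -1))  # t = 0.5, df = 2, p = 2/3
paired_t_test <- function(pre_vec, post_vec) {
  if (length(pre_vec) != length(post_vec)) {
    stop("pre and post vectors must have equal length", call. = FALSE)
  }
  n <- length(pre_vec)
  if (n < 2L) {
    return(list(t = 0, df = max(n - 1L, 0L), p = 1, flag = "insufficient_n"))
  }
  d <- post_vec - pre_vec
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1L
  if (s == 0) {
    if (m == 0) {
      return(list(t = 0, df = df, p = 1, flag = ""))
    }
    return(list(t = sign(m) * Inf, df = df, p = 0, flag = "degenerate"))
  }
  t <- m * sqrt(n) / s
  p <- 2 * stats::pt(-abs(t), df = df)
  list(t = t, df = df, p = p, flag = "")
}

.significance_class <- function(p) {
  ifelse(p < 0.01, "p<0.01", ifelse(p < 0.05, "p<0.05", "ns"))
}

#' Cohort-level evaluation of radiomic dynamics
#'
#' One row per feature observed in at least one patient's paired set:
#' macro-averaged relative difference, dependent paired t-test on the raw
#' feature scores (pairwise-complete across patients), significance class at
#' the 0.05 and 0.01 thresholds, and optionally a Bonferroni-corrected
#' p-value `min(1, p * m)` with `m` the number of evaluated features.
#'
#' @param deviations Deviation records for the whole cohort — the rbind of
#'   [compute_deviations()] outputs across patients.
#' @param bonferroni Add a `p_bonferroni` column (off by default; raw p with
#'   both thresholds is the primary output).
#' @return A data.frame with columns `structure`, `metric`, `n`,
#'   `mean_rel_diff_pct`, `t`, `df`, `p`, `significance`, `flags`
#'   (+ `p_bonferroni`), ordered by (structure, metric).
#' @export
evaluate_cohort <- function(deviations, bonferroni = FALSE) {
  need <- c("patient_id", "structure", "metric", "pre", "post",
            "rel_diff_pct")
  stopifnot(all(need %in% names(deviations)))
  if (nrow(deviations) == 0L) {
    stop("no deviation records to evaluate", call. = FALSE)
  }
  key <- paste(deviations$structure, deviations$metric, sep = ":")
  groups <- split(seq_len(nrow(deviations)), key)

  rows <- lapply(groups, function(idx) {
    g <- deviations[idx, , drop = FALSE]
    tt <- paired_t_test(g$pre, g$post)
    data.frame(
      structure = g$structure[1], metric = g$metric[1],
      n = nrow(g),
      mean_rel_diff_pct = macro_average(g$rel_diff_pct),
      t = tt$t, df = tt$df, p = tt$p,
      significance = .significance_class(tt$p),
      flags = tt$flag,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$structure, out$metric), , drop = FALSE]
  rownames(out) <- NULL
  if (bonferroni) {
    m <- nrow(out)
    out$p_bonferroni <- pmin(1, out$p * m)
  }
  out
}

#' Write per-patient deviation records as CSV
#'
#' @param deviations Output of [compute_deviations()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_deviation_csv <- function(deviations, path) {
  cols <- c("patient_id", "structure", "metric", "pre", "post", "abs_diff",
            "rel_diff_pct", "flags")
  out <- deviations[, cols]
  for (cc in c("pre", "post", "abs_diff", "rel_diff_pct")) {
    out[[cc]] <- signif(out[[cc]], 6)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the cohort evaluation table as CSV
#'
#' @param evaluation Output of [evaluate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_evaluation_csv <- function(evaluation, path) {
  out <- evaluation
  for (cc in intersect(c("mean_rel_diff_pct", "t", "p", "p_bonferroni"),
                       names(out))) {
    out[[cc]] <- signif(out[[cc]], 6)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
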