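# Differential expression: per-feature Welch t-test on log2 values, BH
# correction across all features (coding and lncRNA in one family), and the
# fold-change / FDR selection rule.

#' Per-feature differential expression
#'
#' For every feature, a Welch two-sample t-test of case versus control on the
#' log2 values. `log2fc = mean(case) - mean(control)`; the signed linear fold
#' change is `sign(log2fc) * 2^|log2fc|` (so down-regulation is reported as a
#' negative reciprocal, e.g. -4.52, and `fc = +1` when `log2fc = 0`).
#' q-values are Benjamini-Hochberg adjusted across all features jointly.
#' Features that are constant in both groups with equal means get
#' `p_raw = 1` (a message reports how many).
#'
#' @param x An [expr_set()]; both groups must have >= 2 samples.
#' @return A tibble of class `deg_results` with columns `feature_id`,
#'   `class`, `log2fc`, `fc`, `p_raw`, `q_fdr`, `selected` (all `FALSE` until
#'   [select_degs()] is applied).
#' @export
compute_differential <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  case <- x$values[, x$groups == "case", drop = FALSE]
  ctrl <- x$values[, x$groups == "control", drop = FALSE]
  n1 <- ncol(case)
  n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2) {
    analysis_error("each group needs >= 2 samples for the Welch test")
  }
  m1 <- rowMeans(case)
  m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  # zero variance in both groups: p = 1 when means agree (all-constant
  # feature), 0 when they differ exactly (the noiseless planted-DE limit)
  zerovar <- se2 == 0
  if (any(zerovar)) {
    flat <- zerovar & (m1 - m2) == 0
    if (any(flat)) {
      inform(sprintf("%d all-constant features: p_raw set to 1", sum(flat)))
    }
    p[flat] <- 1
    p[zerovar & !flat] <- 0
  }
  log2fc <- m1 - m2
  q <- p.adjust(p, method = "BH")
  res <- tibble(
    feature_id = rownames(x$values),
    class = unname(x$classes),
    log2fc = unname(log2fc),
    fc = signed_fc(unname(log2fc)),
    p_raw = unname(p),
    q_fdr = unname(q),
    selected = FALSE
  )
  class(res) <- c("deg_results", class(res))
  res
}

#' Signed linear fold change from log2 fold change
#'
#' @param log2fc Numeric vector.
#' @return `sign(log2fc) * 2^|log2fc|`, with `+1` at `log2fc = 0`.
#' @export
signed_fc <- function(log2fc) {
  out <- ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
  out[log2fc == 0] <- 1
  out
}

#' Apply the DEG selection rule
#'
#' A feature is selected iff `|fc| >= fc_min` and `q_fdr <= q_max`, both
#' boundaries inclusive.
#'
#' @param records A `deg_results` tibble from [compute_differential()].
#' @param fc_min Minimum absolute linear fold change (default 1.5).
#' @param q_max Maximum BH-adjusted q-value (default 0.01).
#' @return `records` with the `selected` flag rewritten.
#' @export
select_degs <- function(records, fc_min = 1.5, q_max = 0.01) {
  if (fc_min < 1) parameter_error("fc_min must be >= 1 (linear fold change)")
  if (q_max < 0 || q_max > 1) parameter_error("q_max must lie in [0, 1]")
  records <- mutate(records,
                    selected = abs(.data$fc) >= fc_min & .data$q_fdr <= q_max)
  records
}

#' Identifiers of selected features
#' @param records A `deg_results` tibble after [select_degs()].
#' @return Character vector of selected feature ids.
#' @export
deg_ids <- function(records) {
  records$feature_id[records$selected]
}

#' Partition selected DEGs by feature class
#'
#' @param records A `deg_results` tibble after [select_degs()].
#' @return List with character vectors `coding` and `lncRNA`.
#' @export
split_by_class <- function(records) {
  sel <- filter(records, .data$selected)
  list(
    coding = sel$feature_id[sel$class == "coding"],
    lncRNA = sel$feature_id[sel$class == "lncRNA"]
  )
}
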