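#' Configuration of the screen-level statistics
#'
#' @param alpha FDR significance cutoff (default 0.05).
#' @param test `"moderated_t"` (one-sample t with empirical-Bayes variance
#'   shrinkage across all conditions; default) or `"student_t"`.
#' @param prior_df `"estimate"` to fit the prior degrees of freedom by
#'   moment matching on log sample variances, or a fixed non-negative
#'   number (0 reduces the moderated test to the plain Student t).
#' @param control_label name of the scrambled-control condition.
#' @return List of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, test = c("moderated_t", "student_t"),
                         prior_df = "estimate", control_label = "Scrambled") {
  stopifnot(alpha > 0, alpha < 1)
  test <- match.arg(test)
  if (!identical(prior_df, "estimate"))
    stopifnot(is.numeric(prior_df), length(prior_df) == 1L, prior_df >= 0)
  structure(list(alpha = alpha, test = test, prior_df = prior_df,
                 control_label = control_label),
            class = "stats_config")
}

#' Pool per-cell circularities into per-condition means
#'
#' Cells are pseudo-replicates: all cells of one (gene, siRNA, experiment)
#' condition, pooled over its imaged fields, are reduced to a single mean
#' circularity. The independent experiment is the replication unit for all
#' downstream inference. Input that is already aggregated (has a
#' `mean_circularity` column) passes through unchanged.
#'
#' @param per_cell data.frame with columns `gene`, `sirna`, `experiment`
#'   and either `circularity` (per-cell) or `mean_circularity`
#'   (pre-aggregated).
#' @param config a [stats_config()]; the control must be present in every
#'   experiment.
#' @return Data.frame: `gene`, `sirna`, `experiment`, `mean_circularity`,
#'   `n_cells`.
#' @export
aggregate_condition <- function(per_cell, config = stats_config()) {
  stopifnot(is.data.frame(per_cell),
            all(c("gene", "sirna", "experiment") %in% names(per_cell)))
  if ("mean_circularity" %in% names(per_cell)) {
    agg <- per_cell[, intersect(c("gene", "sirna", "experiment",
                                  "mean_circularity", "n_cells"),
                                names(per_cell))]
    if (!"n_cells" %in% names(agg)) agg$n_cells <- NA_integer_
  } else {
    if (!"circularity" %in% names(per_cell))
      stop("need a 'circularity' or 'mean_circularity' column", call. = FALSE)
    agg <- stats::aggregate(circularity ~ gene + sirna + experiment,
                            data = per_cell, FUN = mean)
    names(agg)[names(agg) == "circularity"] <- "mean_circularity"
    n <- stats::aggregate(circularity ~ gene + sirna + experiment,
                          data = per_cell, FUN = length)
    agg$n_cells <- n$circularity
  }
  for (e in unique(agg$experiment)) {
    if (!any(agg$gene == config$control_label & agg$experiment == e))
      stop(sprintf("control '%s' missing in experiment %s",
                   config$control_label, e), call. = FALSE)
  }
  agg <- agg[order(agg$gene, agg$sirna, agg$experiment), ]
  rownames(agg) <- NULL
  agg
}

#' Normalize conditions within each experiment against the control
#'
#' Divides every condition's mean circularity by that experiment's
#' scrambled-control mean and log2-transforms, removing multiplicative
#' between-experiment (batch) factors. Control rows map to exactly 0.
#'
#' @param agg aggregated table from [aggregate_condition()].
#' @param config a [stats_config()].
#' @return The table with an added `log2_norm` column.
#' @export
normalize_experiment <- function(agg, config = stats_config()) {
  stopifnot(all(c("gene", "experiment", "mean_circularity") %in% names(agg)))
  if (any(agg$mean_circularity <= 0))
    stop("mean circularities must be positive", call. = FALSE)
  agg$log2_norm <- NA_real_
  for (e in unique(agg$experiment)) {
    sel <- agg$experiment == e
    ctrl <- agg$mean_circularity[sel & agg$gene == config$control_label]
    if (length(ctrl) == 0)
      stop(sprintf("control '%s' missing in experiment %s",
                   config$control_label, e), call. = FALSE)
    agg$log2_norm[sel] <- log2(agg$mean_circularity[sel] / mean(ctrl))
  }
  agg
}

# limma-style inverse of the trigamma function (Newton on 1/trigamma).
trigamma_inverse <- function(x) {
  out <- x
  ok <- is.finite(x) & x > 0
  out[!ok & x <= 0] <- Inf
  y <- 0.5 + 1 / x[ok]
  for (i in 1:100) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x[ok]) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(abs(dif / y), na.rm = TRUE) < 1e-14) break
  }
  out[ok] <- y
  out
}

# Moment-matched scaled-F prior for sample variances (Smyth-style):
# s^2 ~ s0^2 * F(df, d0). Fitted on the log variances; returns
# list(d0, s0_2, fallback).
fit_variance_prior <- function(s2, df, fallback_df = 4) {
  keep <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[keep]; df <- df[keep]
  if (length(s2) < 2) {
    s0 <- if (length(s2)) s2 else 1e-4
    return(list(d0 = fallback_df, s0_2 = mean(s0), fallback = TRUE))
  }
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  rhs <- evar - mean(trigamma(df / 2))
  if (!is.finite(rhs) || rhs <= 0) {
    # no positive solution for the prior df: fall back to a fixed prior
    d0 <- fallback_df
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    return(list(d0 = d0, s0_2 = s0_2, fallback = TRUE))
  }
  d0 <- 2 * trigamma_inverse(rhs)
  s0_2 <- if (is.finite(d0)) exp(emean + digamma(d0 / 2) - log(d0 / 2))
          else exp(emean)
  list(d0 = d0, s0_2 = s0_2, fallback = FALSE)
}

#' Test each condition's differential circularity against zero
#'
#' For every (gene, siRNA) the normalized log2 values across experiments
#' are summarized as their mean (the differential circularity) and tested
#' against 0 with either a plain one-sample Student t or a moderated t:
#' the sample variance `s_g^2` (df `d_g = n_g - 1`) is shrunk toward a
#' prior `s_0^2` with prior df `d_0`,
#' `s_tilde^2 = (d0*s0^2 + dg*sg^2) / (d0 + dg)`,
#' `t = mean / (s_tilde/sqrt(n))` on `d0 + dg` degrees of freedom, with
#' `(d0, s0^2)` fitted by matching moments of the log sample variances
#' across all non-control conditions.
#'
#' @param normalized table from [normalize_experiment()].
#' @param config a [stats_config()].
#' @return Data.frame of class `screen_result`: `gene`, `sirna`,
#'   `n_experiments`, `diff_circularity`, `p_value` (control row included
#'   with differential 0). The fitted prior is attached as attribute
#'   `prior`.
#' @export
differential_test <- function(normalized, config = stats_config()) {
  stopifnot("log2_norm" %in% names(normalized))
  key <- interaction(normalized$gene, normalized$sirna, drop = TRUE)
  groups <- split(normalized, key)
  gene <- vapply(groups, function(g) g$gene[1], character(1))
  sirna <- vapply(groups, function(g) g$sirna[1], character(1))
  n <- vapply(groups, nrow, integer(1))
  m <- vapply(groups, function(g) mean(g$log2_norm), numeric(1))
  s2 <- vapply(groups, function(g)
    if (nrow(g) > 1) stats::var(g$log2_norm) else NA_real_, numeric(1))
  is_ctrl <- gene == config$control_label
  if (any(n[!is_ctrl] < 2))
    stop("need at least 2 experiments per condition", call. = FALSE)

  df <- n - 1
  p <- rep(NA_real_, length(n))
  prior <- NULL
  if (config$test == "student_t") {
    if (any(s2[!is_ctrl] == 0))
      stop(paste("zero variance under student_t;",
                 "use test = 'moderated_t'"), call. = FALSE)
    tstat <- m / sqrt(s2 / n)
    p <- 2 * pt(-abs(tstat), df = df)
  } else {
    if (identical(config$prior_df, "estimate")) {
      prior <- fit_variance_prior(s2[!is_ctrl], df[!is_ctrl])
    } else if (config$prior_df == 0) {
      prior <- list(d0 = 0, s0_2 = 0, fallback = FALSE)
    } else {
      fit <- fit_variance_prior(s2[!is_ctrl], df[!is_ctrl])
      prior <- list(d0 = config$prior_df, s0_2 = fit$s0_2, fallback = FALSE)
    }
    d0 <- prior$d0
    s2_use <- ifelse(is.na(s2), 0, s2)
    s_tilde2 <- if (is.finite(d0)) (d0 * prior$s0_2 + df * s2_use) / (d0 + df)
                else rep(prior$s0_2, length(s2_use))
    tstat <- m / sqrt(s_tilde2 / n)
    tstat[s_tilde2 == 0 & m == 0] <- 0
    if (any(s_tilde2 == 0 & m != 0))
      stop("zero moderated variance with non-zero mean", call. = FALSE)
    p <- 2 * pt(-abs(tstat), df = d0 + df)
  }
  # the control is its own reference: differential identically 0
  m[is_ctrl] <- 0
  p[is_ctrl] <- 1
  res <- data.frame(gene = gene, sirna = sirna, n_experiments = n,
                    diff_circularity = m, p_value = p)
  res <- res[order(res$gene, res$sirna), ]
  rownames(res) <- NULL
  attr(res, "prior") <- prior
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' order-preserving and capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Vector of adjusted values of the same length and order.
#' @export
adjust_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- cummin(p[o] * m / seq(m, 1))
  pmin(adj, 1)[ro]
}

#' Classify conditions into positive / negative hits
#'
#' Adds `fdr` (if absent) and `hit_class`: `positive` when the
#' differential circularity is > 0 (cells rounder than the scrambled
#' control, i.e. ramification inhibited) at `fdr < alpha`; `negative` for
#' the symmetric case (enhanced ramification); otherwise
#' `not_significant`.
#'
#' @param results output of [differential_test()].
#' @param config a [stats_config()].
#' @return The results with `fdr` and `hit_class` columns.
#' @export
classify_hits <- function(results, config = stats_config()) {
  stopifnot(all(c("diff_circularity", "p_value") %in% names(results)))
  if (!"fdr" %in% names(results)) results$fdr <- adjust_fdr(results$p_value)
  results$hit_class <- "not_significant"
  sig <- results$fdr < config$alpha
  results$hit_class[sig & results$diff_circularity > 0] <- "positive"
  results$hit_class[sig & results$diff_circularity < 0] <- "negative"
  results
}

#' Validate genes by agreement of independent siRNAs
#'
#' Off-target control: a gene is `validated` only when at least two of its
#' individual siRNAs are significant with the same sign of differential
#' circularity; genes with fewer than two concordant significant siRNAs
#' are `false_positive`.
#'
#' @param results classified single-siRNA results ([classify_hits()]); the
#'   control row is ignored.
#' @param config a [stats_config()].
#' @return Data.frame: `gene`, `n_sirnas`, `n_sig_positive`,
#'   `n_sig_negative`, `status`.
#' @export
validate_gene <- function(results, config = stats_config()) {
  stopifnot("hit_class" %in% names(results))
  res <- results[results$gene != config$control_label, , drop = FALSE]
  out <- lapply(split(res, res$gene), function(g) {
    if (nrow(g) < 2)
      stop(sprintf("gene %s has fewer than 2 siRNA results", g$gene[1]),
           call. = FALSE)
    npos <- sum(g$hit_class == "positive")
    nneg <- sum(g$hit_class == "negative")
    data.frame(gene = g$gene[1], n_sirnas = nrow(g),
               n_sig_positive = npos, n_sig_negative = nneg,
               status = if (npos >= 2 || nneg >= 2) "validated"
                        else "false_positive")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
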