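# Relative-quantification (delta-delta-Ct) and densitometry analysis.

#' Relative expression by the delta-delta-Ct method
#'
#' Technical replicates are averaged on the Ct scale first; then for every
#' sample `dCt = mean Ct(gene) - mean Ct(reference)`, `ddCt = dCt(sample) -
#' dCt(calibrator)` and the fold change is `2^-ddCt` (the calibrator's own
#' fold change is exactly 1). An optional efficiency-adjusted mode replaces
#' the base 2 with `1 + efficiency`; the default follows the standard
#' assumption of perfect doubling per cycle.
#'
#' @param ct data.frame with columns `sample`, `gene`, `ct` (a `replicate`
#'   column is optional); e.g. from [generate_ct_table()].
#' @param reference_gene normalizer gene present in every sample
#'   (default `"GAPDH"`).
#' @param calibrator reference sample (default `"Scrambled"`).
#' @param efficiency optional amplification efficiency in (0, 1\]; when
#'   given, fold changes use base `1 + efficiency` instead of 2.
#' @return Data.frame: `sample`, `gene`, `delta_ct`, `delta_delta_ct`,
#'   `fold_change` for every non-reference gene in every sample.
#' @export
delta_delta_ct <- function(ct, reference_gene = "GAPDH",
                           calibrator = "Scrambled", efficiency = NULL) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  reference_gene <- attr(ct, "reference_gene") %||% reference_gene
  calibrator <- attr(ct, "calibrator") %||% calibrator
  if (any(ct$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  if (!is.null(efficiency))
    stopifnot(efficiency > 0, efficiency <= 1.2)
  base <- if (is.null(efficiency)) 2 else 1 + efficiency
  means <- stats::aggregate(ct ~ sample + gene, data = ct, FUN = mean)
  if (!calibrator %in% means$sample)
    stop(sprintf("calibrator sample '%s' missing", calibrator), call. = FALSE)
  samples <- unique(means$sample)
  ref <- means[means$gene == reference_gene, ]
  if (!all(samples %in% ref$sample))
    stop(sprintf("reference gene '%s' missing in some samples",
                 reference_gene), call. = FALSE)
  ref_ct <- stats::setNames(ref$ct, ref$sample)
  goi <- means[means$gene != reference_gene, , drop = FALSE]
  if (nrow(goi) == 0) stop("no gene of interest in the table", call. = FALSE)
  goi$delta_ct <- goi$ct - ref_ct[goi$sample]
  out <- do.call(rbind, lapply(split(goi, goi$gene), function(g) {
    cal <- g$delta_ct[g$sample == calibrator]
    if (length(cal) != 1)
      stop(sprintf("calibrator sample missing for gene %s", g$gene[1]),
           call. = FALSE)
    g$delta_delta_ct <- g$delta_ct - cal
    g$fold_change <- base^(-g$delta_delta_ct)
    g
  }))
  out <- out[, c("sample", "gene", "delta_ct", "delta_delta_ct",
                 "fold_change")]
  rownames(out) <- NULL
  out
}

#' Loading-control-normalized densitometry ratios
#'
#' For each lane the target band intensity is divided by its loading
#' control (e.g. GAPDH); ratios are then expressed relative to the
#' calibrator lane, whose normalized value is exactly 1.
#'
#' @param lanes data.frame with columns `sample`, `target`, `control`
#'   (band intensities).
#' @param calibrator calibrator lane's sample name.
#' @return The lanes with `ratio` and `normalized` columns.
#' @export
densitometry_ratio <- function(lanes, calibrator = "Scrambled") {
  stopifnot(all(c("sample", "target", "control") %in% names(lanes)))
  if (any(lanes$control <= 0))
    stop("loading-control intensity must be positive", call. = FALSE)
  lanes$ratio <- lanes$target / lanes$control
  cal <- lanes$ratio[lanes$sample == calibrator]
  if (length(cal) != 1)
    stop(sprintf("calibrator lane '%s' missing or duplicated", calibrator),
         call. = FALSE)
  lanes$normalized <- lanes$ratio / cal
  lanes
}
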