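#' Generate a synthetic Ct table with known fold changes
#'
#' Emulates qPCR triplicates for one target gene across treatments: the
#' target-gene Ct of a sample with true fold change `f` relative to the
#' calibrator is `base_ct - log2(f) + eps`, the reference-gene Ct is
#' `ref_ct + eps`, with `eps ~ N(0, noise_sd^2)` per replicate. At
#' `noise_sd = 0` the relative-quantification analysis recovers the planted
#' folds exactly.
#'
#' @param true_fold_changes named positive numeric vector: fold change of
#'   each treated sample relative to the calibrator.
#' @param gene target gene name (default `"BDNF"`).
#' @param base_ct calibrator-sample target-gene Ct (cycles).
#' @param ref_ct reference-gene Ct (cycles).
#' @param noise_sd per-replicate Gaussian Ct noise (cycles).
#' @param n_triplicates technical replicates per (sample, gene).
#' @param reference_gene,calibrator labels of the normalizer gene and
#'   calibrator sample.
#' @param seed integer seed.
#' @return Data.frame of class `ct_table` with columns `sample`, `gene`,
#'   `replicate`, `ct`; attributes `reference_gene`, `calibrator`,
#'   `true_fold_changes`.
#' @export
generate_ct_table <- function(true_fold_changes, gene = "BDNF", base_ct = 24,
                              ref_ct = 18, noise_sd = 0, n_triplicates = 3,
                              reference_gene = "GAPDH",
                              calibrator = "Scrambled", seed = NULL) {
  if (any(true_fold_changes <= 0))
    stop("fold changes must be positive", call. = FALSE)
  if (is.null(names(true_fold_changes)) || any(names(true_fold_changes) == ""))
    stop("true_fold_changes must be a named vector", call. = FALSE)
  stopifnot(n_triplicates >= 1, noise_sd >= 0, base_ct > 0, ref_ct > 0)
  samples <- c(calibrator, names(true_fold_changes))
  folds <- c(1, unname(true_fold_changes))
  with_seed(seed, {
    rows <- list()
    for (i in seq_along(samples)) {
      eps <- function() if (noise_sd > 0) rnorm(n_triplicates, 0, noise_sd) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        sample = samples[i], gene = gene, replicate = seq_len(n_triplicates),
        ct = base_ct - log2(folds[i]) + eps())
      rows[[length(rows) + 1L]] <- data.frame(
        sample = samples[i], gene = reference_gene,
        replicate = seq_len(n_triplicates), ct = ref_ct + eps())
    }
    tbl <- do.call(rbind, rows)
    rownames(tbl) <- NULL
    structure(tbl, reference_gene = reference_gene, calibrator = calibrator,
              true_fold_changes = true_fold_changes,
              class = c("ct_table", "data.frame"))
  })
}
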