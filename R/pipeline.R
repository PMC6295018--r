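# End-to-end screen pipeline and its configuration.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations; serializable to/from JSON with
#' strict key checking.
#'
#' @param morphometry a [morph_config()].
#' @param stats a [stats_config()].
#' @param scratch list of scratch-stage parameters (`window`,
#'   `min_height_frac`, `max_area_frac`).
#' @param seed integer seed recorded in the run manifest.
#' @param log_level `"info"` or `"quiet"`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(morphometry = morph_config(),
                            stats = stats_config(),
                            scratch = list(window = 15, min_height_frac = 0.8,
                                           max_area_frac = 0.9),
                            seed = 1L, log_level = "info") {
  log_level <- match.arg(log_level, c("info", "quiet"))
  structure(list(morphometry = morphometry, stats = stats, scratch = scratch,
                 seed = seed, log_level = log_level),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' Unknown keys in a configuration file are rejected.
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return [write_config()] returns `path` invisibly; [read_config()] a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(lapply(config, unclass)), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("morphometry", "stats", "scratch", "seed", "log_level")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults <- pipeline_config()
  check_keys <- function(got, proto, what) {
    bad <- setdiff(names(got), names(proto))
    if (length(bad))
      stop(sprintf("unknown %s keys: %s", what, paste(bad, collapse = ", ")),
           call. = FALSE)
    got
  }
  morph <- do.call(morph_config,
                   check_keys(raw$morphometry %||% list(),
                              defaults$morphometry, "morphometry"))
  stats_cfg <- do.call(stats_config,
                       check_keys(raw$stats %||% list(), defaults$stats,
                                  "stats"))
  scratch <- utils::modifyList(defaults$scratch,
                               check_keys(raw$scratch %||% list(),
                                          defaults$scratch, "scratch"))
  pipeline_config(morphometry = morph, stats = stats_cfg, scratch = scratch,
                  seed = raw$seed %||% defaults$seed,
                  log_level = raw$log_level %||% defaults$log_level)
}

#' Quantify all fields of a screen
#'
#' Runs the morphometry chain on every layout row and binds the retained
#' cells into one table.
#'
#' @param images named list of image matrices, or a directory of PGM files.
#' @param layout layout table (see [read_layout()]).
#' @param config a [pipeline_config()].
#' @return Per-cell data.frame; per-image thresholds in attribute
#'   `thresholds`, border-cell audit in attribute `audited`.
#' @export
quantify_screen <- function(images, layout, config = pipeline_config()) {
  layout <- validate_layout(layout,
                            if (is.character(images)) images else NULL)
  get_image <- function(id) {
    if (is.character(images)) read_pgm(file.path(images, id))
    else images[[id]] %||% stop_stage("quantify", "image not found: ", id)
  }
  out <- vector("list", nrow(layout))
  thresholds <- numeric(nrow(layout))
  audited <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    img <- get_image(layout$image[i])
    tbl <- analyze_field(img, config$morphometry,
                         metadata = list(image = layout$image[i],
                                         gene = layout$gene[i],
                                         sirna = layout$sirna[i],
                                         experiment = layout$experiment[i],
                                         field = layout$field[i]))
    thresholds[i] <- attr(tbl, "threshold")
    audited[[i]] <- attr(tbl, "audited")
    out[[i]] <- tbl
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "thresholds") <- data.frame(image = layout$image,
                                        threshold = thresholds)
  attr(res, "audited_counts") <- vapply(audited, nrow, integer(1))
  res
}

#' Run the complete screen analysis
#'
#' Composes quantification (optional), per-experiment aggregation and
#' normalization, moderated differential testing, FDR adjustment, hit
#' classification, and multi-siRNA gene validation. Deterministic for a
#' fixed input and configuration.
#'
#' @param images,layout image source and layout (image mode); or
#' @param per_cell a per-cell table (columns `gene`, `sirna`,
#'   `experiment`, `circularity`); or
#' @param aggregated a pre-aggregated table (`gene`, `sirna`,
#'   `experiment`, `mean_circularity`), e.g. from
#'   [generate_screen_tables()].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, all stage tables and a
#'   JSON run manifest are written there.
#' @return List of class `screen_bundle`: `per_cell` (or NULL),
#'   `aggregated`, `normalized`, `results`, `validation`, `manifest`.
#' @export
run_screen <- function(images = NULL, layout = NULL, per_cell = NULL,
                       aggregated = NULL, config = pipeline_config(),
                       out_dir = NULL) {
  stats_cfg <- config$stats
  if (is.null(aggregated)) {
    if (is.null(per_cell)) {
      if (is.null(images) || is.null(layout))
        stop("provide images+layout, per_cell, or aggregated input",
             call. = FALSE)
      per_cell <- quantify_screen(images, layout, config)
    }
    aggregated <- aggregate_condition(per_cell, stats_cfg)
  } else {
    aggregated <- aggregate_condition(aggregated, stats_cfg)
  }
  normalized <- normalize_experiment(aggregated, stats_cfg)
  results <- differential_test(normalized, stats_cfg)
  prior <- attr(results, "prior")
  results$fdr <- adjust_fdr(results$p_value)
  results <- classify_hits(results, stats_cfg)
  single <- results[results$gene != stats_cfg$control_label, , drop = FALSE]
  validation <- if (nrow(single) && all(table(single$gene) >= 2))
    validate_gene(results, stats_cfg) else NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("microscreen")),
    seed = config$seed,
    alpha = stats_cfg$alpha, test = stats_cfg$test,
    control_label = stats_cfg$control_label,
    prior = if (!is.null(prior)) prior[c("d0", "s0_2", "fallback")],
    rows = list(per_cell = if (!is.null(per_cell)) nrow(per_cell),
                aggregated = nrow(aggregated),
                results = nrow(results),
                validation = if (!is.null(validation)) nrow(validation)),
    thresholds = attr(per_cell, "thresholds"))
  bundle <- structure(list(per_cell = per_cell, aggregated = aggregated,
                           normalized = normalized, results = results,
                           validation = validation, manifest = manifest),
                      class = "screen_bundle")
  if (!is.null(out_dir)) write_results(bundle, out_dir)
  bundle
}

#' Write a screen result bundle to disk
#'
#' @param bundle a `screen_bundle` from [run_screen()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "screen_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) if (!is.null(x))
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  wr(bundle$per_cell, "per_cell.csv")
  wr(bundle$aggregated, "aggregated.csv")
  wr(bundle$normalized, "normalized.csv")
  wr(bundle$results, "screen_results.csv")
  wr(bundle$validation, "gene_validation.csv")
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.screen_bundle <- function(x, ...) {
  cat(sprintf("<screen_bundle> %d conditions, %d results",
              nrow(x$aggregated), nrow(x$results)))
  if (!is.null(x$validation))
    cat(sprintf(", %d genes validated",
                sum(x$validation$status == "validated")))
  cat("\n")
  invisible(x)
}
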