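#' Describe a simulated siRNA screen
#'
#' The default geometry mirrors the screening campaign the package is built
#' for: 157 target genes, three individual siRNAs per gene, three
#' independent experiments, three imaged fields per condition, with a
#' scrambled non-targeting control present in every experiment.
#'
#' @param n_genes number of target genes.
#' @param sirnas_per_gene individual siRNAs per gene.
#' @param n_experiments independent biological replicates.
#' @param fields_per_condition imaged fields pooled per condition.
#' @param cells_per_field cells per field (image-level simulations).
#' @param control_label name of the scrambled control condition.
#' @param effect_map named numeric vector of planted log2 circularity
#'   shifts (names must be gene names from the design; unnamed genes get 0).
#' @param noise_sd between-replicate SD of log2 mean circularity.
#' @param control_mean mean circularity of the control phenotype
#'   (CM-treated, elongated cells; ~0.45 on the 0-1 circularity scale).
#' @param seed integer seed.
#' @return Object of class `screen_design`.
#' @export
screen_design <- function(n_genes = 157, sirnas_per_gene = 3,
                          n_experiments = 3, fields_per_condition = 3,
                          cells_per_field = 15, control_label = "Scrambled",
                          effect_map = NULL, noise_sd = 0.3,
                          control_mean = 0.45, seed = NULL) {
  stopifnot(n_genes >= 1, sirnas_per_gene >= 1, n_experiments >= 1,
            fields_per_condition >= 1, cells_per_field >= 1,
            noise_sd >= 0, control_mean > 0)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  effects <- stats::setNames(rep(0, n_genes), genes)
  if (!is.null(effect_map)) {
    if (is.null(names(effect_map)) || any(names(effect_map) == ""))
      stop("effect_map must be a named numeric vector", call. = FALSE)
    if (control_label %in% names(effect_map)) {
      if (effect_map[[control_label]] != 0)
        stop("the control must have planted effect 0", call. = FALSE)
      effect_map <- effect_map[names(effect_map) != control_label]
    }
    unknown <- setdiff(names(effect_map), genes)
    if (length(unknown))
      stop("effect_map references unknown genes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    effects[names(effect_map)] <- effect_map
  }
  structure(list(n_genes = as.integer(n_genes),
                 sirnas_per_gene = as.integer(sirnas_per_gene),
                 n_experiments = as.integer(n_experiments),
                 fields_per_condition = as.integer(fields_per_condition),
                 cells_per_field = as.integer(cells_per_field),
                 control_label = control_label, genes = genes,
                 effects = effects, noise_sd = noise_sd,
                 control_mean = control_mean, seed = seed),
            class = "screen_design")
}

#' Simulate a screen at the aggregated-table level
#'
#' Fast statistical twin of the imaging screen: for every (gene, siRNA,
#' experiment) the mean circularity is drawn as
#' `control_mean * 2^(effect + eps)` with `eps ~ N(0, noise_sd^2)`; the
#' scrambled control is drawn once per experiment with effect 0. The output
#' schema matches the aggregated output of the morphometry stage, so the
#' screen statistics consume either source interchangeably.
#'
#' @param design a [screen_design()].
#' @return Data.frame with columns `gene`, `sirna`, `experiment`,
#'   `mean_circularity` (controls have `sirna = "ctrl"`); the design is
#'   attached as attribute `design`.
#' @export
generate_screen_tables <- function(design) {
  stopifnot(inherits(design, "screen_design"))
  with_seed(design$seed, {
    grid <- expand.grid(sirna = sprintf("#%d", seq_len(design$sirnas_per_gene)),
                        gene = design$genes,
                        experiment = seq_len(design$n_experiments),
                        stringsAsFactors = FALSE)
    grid <- grid[, c("gene", "sirna", "experiment")]
    ctrl <- data.frame(gene = design$control_label, sirna = "ctrl",
                       experiment = seq_len(design$n_experiments))
    tbl <- rbind(grid, ctrl)
    eff <- ifelse(tbl$gene == design$control_label, 0, design$effects[tbl$gene])
    eps <- if (design$noise_sd > 0) rnorm(nrow(tbl), 0, design$noise_sd) else 0
    tbl$mean_circularity <- design$control_mean * 2^(eff + eps)
    rownames(tbl) <- NULL
    attr(tbl, "design") <- design
    tbl
  })
}

# Invert the analytic ellipse circularity to an aspect ratio (C in (0, 1]).
aspect_for_circularity <- function(target_c) {
  stopifnot(target_c > 0, target_c <= 1)
  if (target_c >= 1 - 1e-12) return(1)
  f <- function(ar) shape_spec("ellipse", 10, aspect_ratio = ar)$target_circularity - target_c
  stats::uniroot(f, c(1, 400), tol = 1e-10)$root
}

#' Simulate a screen at the image level
#'
#' Renders every field of a (small) screen design as a synthetic image.
#' Cells are ellipses whose aspect ratio encodes the condition's target
#' circularity `control_mean * 2^(effect + eps)`, with a per-condition
#' replicate noise draw `eps` and per-cell jitter on the log2 scale, so the
#' planted per-gene log2 shifts propagate through segmentation and
#' measurement to the screen statistics.
#'
#' @param design a [screen_design()] (keep `n_genes` small; every
#'   condition-field becomes an image).
#' @param image_size per-field image size in pixels.
#' @param cell_radius_px equal-area disk radius of each cell.
#' @param cell_jitter_sd per-cell log2 circularity jitter.
#' @param noise_sd image intensity noise SD.
#' @return List with `images` (named list of matrices), `layout`
#'   (data.frame: `image`, `gene`, `sirna`, `experiment`, `field`) and the
#'   `design`.
#' @export
generate_screen_images <- function(design, image_size = c(160, 160),
                                   cell_radius_px = 9, cell_jitter_sd = 0.1,
                                   noise_sd = 4) {
  stopifnot(inherits(design, "screen_design"))
  with_seed(design$seed, {
    conds <- rbind(
      expand.grid(sirna = sprintf("#%d", seq_len(design$sirnas_per_gene)),
                  gene = design$genes, stringsAsFactors = FALSE
                  )[, c("gene", "sirna")],
      data.frame(gene = design$control_label, sirna = "ctrl"))
    images <- list()
    layout <- list()
    for (e in seq_len(design$n_experiments)) {
      for (ci in seq_len(nrow(conds))) {
        g <- conds$gene[ci]; s <- conds$sirna[ci]
        eff <- if (g == design$control_label) 0 else design$effects[[g]]
        eps <- if (design$noise_sd > 0) rnorm(1, 0, design$noise_sd) else 0
        cond_c <- design$control_mean * 2^(eff + eps)
        for (f in seq_len(design$fields_per_condition)) {
          cellc <- cond_c * 2^(if (cell_jitter_sd > 0)
            rnorm(design$cells_per_field, 0, cell_jitter_sd) else 0)
          cellc <- pmin(pmax(cellc, 0.05), 1)
          specs <- lapply(cellc, function(cc)
            shape_spec("ellipse", cell_radius_px,
                       aspect_ratio = aspect_for_circularity(cc)))
          fld <- generate_field(specs, image_size = image_size, n_border = 0,
                                noise_sd = noise_sd, seed = NULL)
          id <- sprintf("%s_%s_e%d_f%d.pgm", gsub("[^A-Za-z0-9]", "", g),
                        gsub("[^A-Za-z0-9]", "", s), e, f)
          images[[id]] <- fld$image
          layout[[length(layout) + 1L]] <-
            data.frame(image = id, gene = g, sirna = s, experiment = e,
                       field = f)
        }
      }
    }
    list(images = images, layout = do.call(rbind, layout), design = design)
  })
}
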