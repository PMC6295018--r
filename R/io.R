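# Plain-text image and table I/O.
#
# Images are exchanged as ASCII PGM (portable graymap, magic "P2"), a
# single-channel text format that round-trips 8- and 16-bit grayscale
# without binary dependencies.

#' Write a grayscale image as ASCII PGM
#'
#' @param image numeric matrix (intensities are rounded).
#' @param path output file path (conventionally `.pgm`).
#' @param maxval maximum gray value (255 for 8-bit, 65535 for 16-bit).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, maxval = 255) {
  stopifnot(is.matrix(image), maxval %in% c(255, 65535))
  img <- round(pmin(pmax(image, 0), maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  writeLines(apply(img, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ASCII PGM image
#'
#' @param path file path.
#' @return Numeric matrix; attribute `maxval` carries the bit depth.
#' @export
read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^\\s*#", txt)]
  if (!identical(trimws(txt[1]), "P2"))
    stop("not an ASCII PGM (P2) file: ", path, call. = FALSE)
  vals <- scan(text = paste(txt[-1], collapse = "\n"), what = numeric(),
               quiet = TRUE)
  nc <- vals[1]; nr <- vals[2]; maxval <- vals[3]
  px <- vals[-(1:3)]
  if (length(px) != nr * nc)
    stop("corrupt PGM: pixel count mismatch in ", path, call. = FALSE)
  img <- matrix(px, nrow = nr, ncol = nc, byrow = TRUE)
  attr(img, "maxval") <- maxval
  img
}

layout_columns <- c("image", "gene", "sirna", "experiment", "field")

#' Read and validate a screen layout table
#'
#' The layout maps image files to their condition: columns `image`,
#' `gene`, `sirna`, `experiment`, `field` (exactly; extra or missing
#' columns are an error). The (gene, sirna, experiment, field) combination
#' must be unique.
#'
#' @param path CSV file path.
#' @param check_files if a directory, every `image` entry must exist in it.
#' @return Validated data.frame.
#' @export
read_layout <- function(path, check_files = NULL) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_layout(tbl, check_files)
}

# shared validator for layouts from file or memory
validate_layout <- function(tbl, check_files = NULL) {
  missing_cols <- setdiff(layout_columns, names(tbl))
  extra <- setdiff(names(tbl), layout_columns)
  if (length(missing_cols) || length(extra))
    stop(sprintf("layout schema mismatch: missing [%s], extra [%s]",
                 paste(missing_cols, collapse = ", "),
                 paste(extra, collapse = ", ")), call. = FALSE)
  key <- do.call(paste, c(tbl[c("gene", "sirna", "experiment", "field")],
                          sep = "\r"))
  if (anyDuplicated(key))
    stop("layout contains duplicate (gene, sirna, experiment, field) rows",
         call. = FALSE)
  if (!is.null(check_files)) {
    paths <- file.path(check_files, tbl$image)
    bad <- tbl$image[!file.exists(paths)]
    if (length(bad))
      stop("layout references missing image files: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  tbl
}

#' Write a screen layout table
#' @param layout data.frame with the layout schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  validate_layout(layout)
  utils::write.csv(layout, path, row.names = FALSE)
  invisible(path)
}
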