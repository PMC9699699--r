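#' Write view traces to CSV
#'
#' One row per cell; a comment header line records the sampling rate and
#' stage label so the file is self-describing.
#'
#' @param view a \code{synthetic_view}, or a cells x time matrix.
#' @param path output file.
#' @param fs,stage required when \code{view} is a bare matrix.
#' @param background scalar background fluorescence recorded in the header
#'   (taken from the preset for synthetic views).
#' @export
write_traces_csv <- function(view, path, fs = NULL, stage = NULL,
                             background = 0) {
  if (inherits(view, "synthetic_view")) {
    mat <- view$traces
    fs <- view$fs
    stage <- paste0(view$preset$stage_label, ":", view$preset$condition)
    background <- view$preset$background_F
  } else mat <- view
  if (is.null(fs)) stop("fs required")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g stage=%s bg=%g", fs,
                     if (is.null(stage)) "NA" else stage, background),
             con)
  df <- data.frame(cell = rownames(mat) %||% paste0("cell", seq_len(nrow(mat))),
                   mat, check.names = FALSE)
  colnames(df) <- c("cell", paste0("s", seq_len(ncol(mat))))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read view traces from CSV
#'
#' @param path file written by \code{\link{write_traces_csv}}.
#' @return list with \code{traces} (matrix), \code{fs}, \code{stage}.
#' @export
read_traces_csv <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#")) stop("missing '# fs=... stage=...' header")
  fs <- as.numeric(sub(".*fs=([0-9.eE+-]+).*", "\\1", header))
  stage <- sub(".*stage=(\\S+).*", "\\1", header)
  bg <- if (grepl("bg=", header)) {
    as.numeric(sub(".*bg=([0-9.eE+-]+).*", "\\1", header))
  } else 0
  df <- utils::read.csv(path, skip = 1, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  list(traces = mat, fs = fs, stage = stage, background = bg)
}

#' Write an event table to CSV
#'
#' One row per event: cell, t_peak, amplitude, fwhm, t_on50, t_off50.
#'
#' @param tables named list of \code{event_table}s (names = cell ids), or
#'   a single table.
#' @param path output file.
#' @export
write_events_csv <- function(tables, path) {
  if (inherits(tables, "event_table")) tables <- list(cell1 = tables)
  rows <- lapply(names(tables), function(id) {
    tab <- tables[[id]]
    if (!nrow(tab)) return(NULL)
    data.frame(cell = id, tab[, c("t_peak", "amplitude", "fwhm",
                                  "t_on50", "t_off50")])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cell = character(0), t_peak = numeric(0),
                      amplitude = numeric(0), fwhm = numeric(0),
                      t_on50 = numeric(0), t_off50 = numeric(0))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic image (and its masks) as TIFF
#'
#' The intensity image is scaled to [0,1] by its maximum and written as a
#' single-page grayscale TIFF; each mask goes to \code{<stem>_mask_<name>.tif}
#' as 0/1.
#'
#' @param img a \code{synthetic_image}.
#' @param path output path for the intensity image (".tif").
#' @param masks write the mask TIFFs too (default TRUE).
#' @export
write_image_tiff <- function(img, path, masks = TRUE) {
  px <- img$pixels
  px <- pmax(px, 0) / max(px)
  tiff::writeTIFF(px, path, bits.per.sample = 16)
  if (masks) {
    stem <- sub("\\.tiff?$", "", path)
    for (nm in names(img$masks)) {
      tiff::writeTIFF(matrix(as.numeric(img$masks[[nm]]), nrow(px)),
                      paste0(stem, "_mask_", nm, ".tif"),
                      bits.per.sample = 8)
    }
  }
  invisible(path)
}

#' Read a grayscale TIFF as a numeric matrix
#'
#' @param path TIFF file.
#' @return numeric matrix in [0,1].
#' @export
read_image_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}
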