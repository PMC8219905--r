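# Electrode montage: 31 channels of the 10-20 system placed on the scalp
# sphere. Default positions come from a standard 10-20 table shipped as a
# plain-text .sfp file of unit direction vectors (Cz at the apex by
# convention), scaled to the scalp radius.

#' Read an .sfp-style electrode table
#'
#' Whitespace-delimited `label x y z` rows, coordinates in mm (or unit
#' vectors for the shipped standard table).
#' @param path file path.
#' @return data.frame with columns label, x, y, z.
#' @export
read_sfp <- function(path) {
  df <- utils::read.table(path, header = FALSE, col.names = c("label", "x", "y", "z"),
                          stringsAsFactors = FALSE)
  df$label <- as.character(df$label)
  df
}

#' Write an .sfp-style electrode table
#' @param montage a `montage` object or data.frame with label/x/y/z.
#' @param path output file.
#' @export
write_sfp <- function(montage, path) {
  df <- if (inherits(montage, "montage")) {
    data.frame(label = montage$labels, x = montage$positions[, 1],
               y = montage$positions[, 2], z = montage$positions[, 3])
  } else {
    montage
  }
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build an electrode montage
#'
#' The default layout is the 31-channel 10-20 set (Fp1 ... Fp2) at standard
#' angular positions on a sphere of `radius` mm, with Cz at the apex. An
#' explicit table (data.frame with label/x/y/z in mm) can be supplied instead,
#' in which case coordinates are used as-is.
#'
#' @param layout "standard31" or a data.frame with columns label, x, y, z.
#' @param radius scalp sphere radius in mm used for the standard layout
#'   (default 92; must exceed the source-space radius).
#' @return object of class `montage`: `labels` (length q), `positions`
#'   (q x 3, mm).
#' @export
build_montage <- function(layout = "standard31", radius = 92) {
  if (is.character(layout) && identical(layout, "standard31")) {
    path <- system.file("extdata", "montage1020_31.sfp", package = "esicnn",
                        mustWork = TRUE)
    df <- read_sfp(path)
    pos <- unit_rows(as.matrix(df[, c("x", "y", "z")])) * radius
  } else if (is.data.frame(layout)) {
    df <- layout
    stopifnot(all(c("label", "x", "y", "z") %in% names(df)))
    pos <- as.matrix(df[, c("x", "y", "z")])
  } else {
    stop("layout must be \"standard31\" or a data.frame")
  }
  labels <- as.character(df$label)
  if (anyDuplicated(labels)) stop("duplicate electrode labels")
  dimnames(pos) <- NULL
  structure(list(labels = labels, positions = pos), class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d electrodes (%s ...)\n", length(x$labels),
              paste(utils::head(x$labels, 4), collapse = ", ")))
  invisible(x)
}

#' Number of electrodes in a montage
#' @param montage a `montage`.
#' @return integer count.
#' @export
n_electrodes <- function(montage) length(montage$labels)
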