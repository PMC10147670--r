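SPOT_COLUMNS <- c("fov", "gene", "channel", "z_um", "y_um", "x_um")

# Validate and class a raw data frame of detected spots.
as_spot_table <- function(df) {
  missing_cols <- setdiff(SPOT_COLUMNS, names(df))
  if (length(missing_cols))
    stop_fmt("spot table is missing column(s): %s", paste(missing_cols, collapse = ", "))
  df <- df[SPOT_COLUMNS]
  for (col in c("fov", "gene", "channel")) {
    df[[col]] <- as.character(df[[col]])
    bad <- which(is.na(df[[col]]) | !nzchar(df[[col]]))
    if (length(bad))
      stop_fmt("spot table: empty '%s' at row %d", col, bad[1])
  }
  for (col in c("z_um", "y_um", "x_um")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop_fmt("spot table: non-numeric '%s' at row %d", col,
               if (length(bad)) bad[1] else 1L)
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop_fmt("spot table: '%s' must be finite and >= 0 (row %d has %s)",
               col, bad[1], format(v[bad[1]]))
  }
  # one channel per gene within a fov
  key <- unique(df[c("fov", "gene", "channel")])
  dup <- duplicated(key[c("fov", "gene")])
  if (any(dup))
    stop_fmt("gene '%s' maps to several channels within fov '%s'",
             key$gene[dup][1], key$fov[dup][1])
  rownames(df) <- NULL
  class(df) <- c("spot_table", "data.frame")
  df
}

#' Read a table of detected RNA spots
#'
#' Reads a delimited text file with header
#' `fov,gene,channel,z_um,y_um,x_um` (comma or tab separated): one row per
#' detected spot, coordinates in physical micrometres, `(z, y, x)` axis
#' order. Input is validated strictly — missing columns, non-numeric or
#' negative coordinates, and genes imaged in two channels within one field of
#' view are rejected with the offending row named.
#'
#' @param path Path to the file.
#' @return A `spot_table` (validated data frame), row order preserved.
#' @seealso [write_spot_table()], [filter_cross_channel()]
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) stop_fmt("no such spot table: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  as_spot_table(df)
}

#' Write a spot table
#'
#' @param spots A `spot_table` (or data frame with the same columns).
#' @param path Output path; comma-separated with header.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  spots <- as_spot_table(as.data.frame(spots))
  utils::write.table(spots, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("spot_table: %d spots, %d gene(s), %d channel(s), %d fov(s)\n",
              nrow(x), length(unique(x$gene)), length(unique(x$channel)),
              length(unique(x$fov))))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 5))
  invisible(x)
}
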