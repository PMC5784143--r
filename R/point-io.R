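#' @include AllClasses.R
NULL

# Read a delimited/spreadsheet table into a data.frame of raw columns.
# Header rows are auto-skipped when non-numeric; comment lines with '#'
# are dropped.
.readTable <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xls", "xlsx")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading '", ext, "' files requires the readxl package")
    df <- as.data.frame(readxl::read_excel(path, col_names = FALSE,
                                           .name_repair = "minimal"))
    return(df)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no points: '", path, "' contains no data rows")
  # delimiter: comma, tab, semicolon or whitespace - whichever splits most
  delims <- c(",", "\t", ";", "[[:space:]]+")
  counts <- vapply(delims, function(d)
    length(strsplit(lines[[length(lines)]], d)[[1]]), integer(1))
  delim <- delims[[which.max(counts)]]
  parts <- strsplit(lines, delim)
  ncols <- max(lengths(parts))
  mat <- t(vapply(parts, function(p) {
    length(p) <- ncols
    p
  }, character(ncols)))
  as.data.frame(mat, stringsAsFactors = FALSE)
}

#' Read a centroid table into a point pattern
#'
#' Ingestion boundary of the toolkit: reads comma/tab/whitespace-separated
#' text (`.csv`, `.dat`, `.txt`, `.tsv`) or spreadsheet files (`.xls`,
#' `.xlsx`, via readxl) of object centroids, one object per row. The first
#' two numeric columns are taken as x and y; a third numeric column is
#' taken as per-object radius when `radiusColumn = TRUE`. A non-numeric
#' header row is skipped automatically.
#'
#' Unit conversion happens exactly once, here: when `pixelSize` is given,
#' all coordinates (and radii) are multiplied by it. Image-convention input
#' (y increasing downwards) is converted to the package's lower-left-origin
#' convention with `yFlip = TRUE`.
#'
#' @param path path to the table.
#' @param window an [ObsWindow-class] in the *final* (post-conversion)
#'   unit, or `NULL` to use the tight bounding box of the points. Points
#'   outside an explicit window are an error.
#' @param pixelSize optional length per pixel; coordinates are multiplied
#'   into physical units.
#' @param yFlip flip the y axis (image convention to math convention).
#' @param radiusColumn treat a third numeric column as object radius.
#' @param label sample label; defaults to the file name.
#' @return A [PointPattern-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("x,y", "0,0", "1,0", "0,1"), f)
#' p <- readPattern(f)
#' nPoints(p)
#' @export
readPattern <- function(path, window = NULL, pixelSize = NULL,
                        yFlip = FALSE, radiusColumn = FALSE,
                        label = basename(path)) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  df <- .readTable(path)
  num <- suppressWarnings(
    as.data.frame(lapply(df, function(col) as.numeric(as.character(col)))))
  # auto-skip leading non-numeric (header) rows
  rowOk <- rowSums(!is.na(num)) >= 2L
  firstData <- which(rowOk)
  if (!length(firstData)) stop("no points: no numeric rows in '", path, "'")
  num <- num[firstData[1]:nrow(num), , drop = FALSE]
  bad <- rowSums(!is.na(num)) < 2L
  if (any(bad))
    stop("non-numeric rows in '", path, "' (rows ",
         paste(which(bad), collapse = ", "), " after header)")
  numericCols <- which(colSums(is.na(num)) == 0L)
  if (length(numericCols) < 2L)
    stop("need two fully numeric columns in '", path, "'")
  x <- num[[numericCols[1]]]
  y <- num[[numericCols[2]]]
  radii <- numeric(0)
  if (radiusColumn) {
    if (length(numericCols) < 3L)
      stop("radiusColumn = TRUE but no third numeric column in '", path, "'")
    radii <- num[[numericCols[3]]]
  }
  if (yFlip) y <- -y
  if (!is.null(pixelSize)) {
    stopifnot(is.numeric(pixelSize), pixelSize > 0)
    x <- x * pixelSize
    y <- y * pixelSize
    if (length(radii)) radii <- radii * pixelSize
  }
  if (!is.null(window)) {
    if (!all(.inWindow(cbind(x, y), window,
                       .boundary_rtol * windowDiagonal(window))))
      stop("points outside the supplied observation window")
  }
  pointPattern(x, y, window = window, radii = radii,
               pixelSize = if (is.null(pixelSize)) NA_real_ else pixelSize,
               label = label)
}

#' Write a point pattern as a centroid table
#'
#' Writes the `x,y[,radius]` comma-separated format that [readPattern()]
#' reads back; coordinates round-trip at full double precision.
#'
#' @param pattern a [PointPattern-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writePattern <- function(pattern, path) {
  xy <- coordinates(pattern)
  df <- data.frame(x = xy[, 1], y = xy[, 2])
  if (length(patternRadii(pattern))) df$radius <- patternRadii(pattern)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read metric tables
#'
#' `writeMetrics` writes keyed records (a data.frame, or a list of named
#' lists sharing one schema) as a comma-separated table with a header row;
#' `readMetrics` reads such a table back. Values round-trip at full
#' precision.
#'
#' @param records a data.frame or list of named lists with a common schema.
#' @param path file path.
#' @return `writeMetrics`: invisibly, `path`; `readMetrics`: a data.frame.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeMetrics(data.frame(N = 3, lambda = 3.0), f)
#' readMetrics(f)
#' @export
writeMetrics <- function(records, path) {
  if (!is.data.frame(records)) {
    if (!length(records)) stop("cannot infer a schema from zero records")
    keys <- names(records[[1]])
    same <- vapply(records, function(r) identical(names(r), keys), logical(1))
    if (!all(same)) stop("records do not share a schema")
    records <- do.call(rbind, lapply(records, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  num <- vapply(records, is.numeric, logical(1))
  records[num] <- lapply(records[num], function(v)
    vapply(v, function(x) format(x, digits = 17), character(1)))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMetrics
#' @export
readMetrics <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a JSON run manifest
#'
#' Records the window, unit assumption, seeds and every defaulted
#' parameter of a run, so results can be reproduced bit-identically.
#'
#' @param manifest a named list.
#' @param path output path (`.json`).
#' @return Invisibly, `path`.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
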