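# On-disk formats.  All artifacts are plain UTF-8 CSV so they diff cleanly
# and round-trip bit-exactly:
#   * measurement matrix: optional "#step:" provenance comments, row 0 = IRM
#     axis with an empty (0,0) cell, column 0 = RT axis;
#   * feature matrix: "sample_id,Peak_0000,...";
#   * labels: "sample_id,label";
#   * layer annotation: "name,rt_center,irm_center,rt_radius,irm_radius";
#   * peak list: "sample_id,rt,irm,intensity,method".

# full double precision; survives read-back exactly
fmt_num <- function(x) sprintf("%.17g", x)

parse_num <- function(x, what, line) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v) & !(trimws(x) %in% c("", "NA")))) {
    stop(sprintf("non-numeric %s at line %d", what, line))
  }
  v
}

#' Read a measurement matrix file
#'
#' Parses the CSV measurement dialect: optional leading
#' `#step:<name> key=value ...` provenance comment lines, a header row whose
#' first cell is empty and whose remaining cells are the IRM axis, and data
#' rows whose first cell is the RT coordinate.
#'
#' @param source path to the file.
#' @param sample_id sample identifier; defaults to the filename stem.
#' @return a [new_measurement()] object.
#' @export
read_measurement <- function(source, sample_id = NULL) {
  lines <- readLines(source, encoding = "UTF-8")
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(source))
  }
  prov_lines <- grep("^#", lines)
  provenance <- lapply(lines[prov_lines], parse_provenance_line)
  body <- lines[setdiff(seq_along(lines), prov_lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop("measurement file has no data rows")
  header <- strsplit(body[[1]], ",", fixed = TRUE)[[1]]
  irm_axis <- parse_num(header[-1], "IRM header value", line = 1L)
  ncols <- length(irm_axis)
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != ncols + 1L)) {
    bad <- which(widths != ncols + 1L)[1]
    stop(sprintf("ragged row at line %d: expected %d cells, found %d",
                 bad + 1L, ncols + 1L, widths[bad]))
  }
  rt_axis <- numeric(length(rows))
  intensity <- matrix(0, nrow = length(rows), ncol = ncols)
  for (i in seq_along(rows)) {
    vals <- parse_num(rows[[i]], "cell", line = i + 1L)
    rt_axis[i] <- vals[1]
    intensity[i, ] <- vals[-1]
  }
  if (any(diff(rt_axis) <= 0)) stop("rt axis not strictly increasing")
  if (any(diff(irm_axis) <= 0)) stop("irm axis not strictly increasing")
  new_measurement(sample_id, rt_axis, irm_axis, intensity,
                  provenance = provenance)
}

parse_provenance_line <- function(line) {
  if (!startsWith(line, "#step:")) {
    return(list(step = sub("^#\\s*", "", line), params = list()))
  }
  rest <- sub("^#step:", "", line)
  tokens <- strsplit(trimws(rest), "\\s+")[[1]]
  params <- list()
  if (length(tokens) > 1) {
    for (tok in tokens[-1]) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
      val <- suppressWarnings(as.numeric(kv[2]))
      params[[kv[1]]] <- if (is.na(val)) kv[2] else val
    }
  }
  list(step = tokens[1], params = params)
}

#' Write a measurement matrix file
#'
#' Inverse of [read_measurement()]: emits one `#step:` comment line per
#' provenance entry (none for a raw measurement) followed by the axis header
#' and intensity rows at full numeric precision.
#'
#' @param m a `mcc_measurement`.
#' @param dest destination path.
#' @return `dest`, invisibly.
#' @export
write_measurement <- function(m, dest) {
  validate_measurement(m)
  lines <- character(0)
  for (p in m$provenance) {
    kv <- if (length(p$params)) {
      paste0(" ", paste(names(p$params),
                        vapply(p$params, function(v) {
                          if (is.numeric(v)) fmt_num(v) else as.character(v)
                        }, ""),
                        sep = "=", collapse = " "))
    } else ""
    lines <- c(lines, paste0("#step:", p$step, kv))
  }
  lines <- c(lines, paste0(",", paste(fmt_num(m$irm_axis), collapse = ",")))
  for (i in seq_along(m$rt_axis)) {
    lines <- c(lines, paste(c(fmt_num(m$rt_axis[i]), fmt_num(m$intensity[i, ])),
                            collapse = ","))
  }
  writeLines(lines, dest, useBytes = TRUE)
  invisible(dest)
}

#' Read a feature matrix
#'
#' First column `sample_id`, remaining columns peak ids. Blank cells are
#' read as 0 (peak absent). Peak ids of the form `Peak_%04d` are assigned
#' the cell-center coordinates of the supplied probe-clustering grid.
#'
#' @param source path to the CSV file.
#' @param grid a [build_grid()] spec used to decode `Peak_%04d` ids into
#'   coordinates; `NULL` leaves coordinates `NA`.
#' @return a [new_feature_matrix()].
#' @export
read_feature_matrix <- function(source, grid = build_grid()) {
  df <- utils::read.csv(source, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (names(df)[1] != "sample_id") stop("first column must be sample_id")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  if (anyDuplicated(names(df)[-1])) stop("duplicate peak-id columns")
  ids <- df$sample_id
  vals <- as.matrix(df[, -1, drop = FALSE])
  vals[trimws(vals) == ""] <- "0"
  storage.mode(vals) <- "double"
  vals[is.na(vals)] <- 0
  rownames(vals) <- ids
  coords <- decode_peak_coords(colnames(vals), grid)
  new_feature_matrix(vals, coords, params = list(source = "imported"))
}

#' Write a feature matrix
#'
#' @param fm a `mcc_feature_matrix`.
#' @param dest destination path.
#' @return `dest`, invisibly.
#' @export
write_feature_matrix <- function(fm, dest) {
  header <- paste(c("sample_id", fm$peak_ids), collapse = ",")
  rows <- vapply(seq_along(fm$sample_ids), function(i) {
    paste(c(fm$sample_ids[i], fmt_num(fm$values[i, ])), collapse = ",")
  }, "")
  writeLines(c(header, rows), dest, useBytes = TRUE)
  invisible(dest)
}

#' Read a class-label table
#'
#' @param source path to a `sample_id,label` CSV.
#' @param require_binary if `TRUE`, error unless exactly two distinct labels
#'   are present (classification runs are binary case-control).
#' @return named character vector of labels keyed by sample id.
#' @export
read_labels <- function(source, require_binary = FALSE) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("labels file must have columns sample_id,label")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in labels file")
  labels <- stats::setNames(df$label, df$sample_id)
  if (require_binary) check_binary_labels(labels)
  labels
}

check_binary_labels <- function(labels) {
  k <- length(unique(labels))
  if (k != 2) {
    stop(sprintf("classification requires exactly 2 classes, found %d", k))
  }
  invisible(labels)
}

#' Write a class-label table
#' @param labels named character vector keyed by sample id.
#' @param dest destination path.
#' @return `dest`, invisibly.
#' @export
write_labels <- function(labels, dest) {
  writeLines(c("sample_id,label",
               paste(names(labels), labels, sep = ",")),
             dest, useBytes = TRUE)
  invisible(dest)
}

#' Read a layer / annotation file
#'
#' Each row names a rectangle in the (RT, IRM) plane inside which a peak
#' intensity is read (VisualNow annotation convention).
#'
#' @param source path to a `name,rt_center,irm_center,rt_radius,irm_radius`
#'   CSV.
#' @return data.frame with those five columns.
#' @export
read_layer <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("name", "rt_center", "irm_center", "rt_radius", "irm_radius")
  if (!all(need %in% names(df))) {
    stop("layer file must have columns ", paste(need, collapse = ","))
  }
  df <- df[, need, drop = FALSE]
  if (nrow(df)) {
    if (anyDuplicated(df$name)) stop("duplicate rectangle names in layer file")
    if (any(df$rt_radius <= 0) || any(df$irm_radius <= 0)) {
      stop("layer radii must be strictly positive")
    }
  }
  df
}

#' Write a layer / annotation file
#' @param layer data.frame as returned by [read_layer()].
#' @param dest destination path.
#' @return `dest`, invisibly.
#' @export
write_layer <- function(layer, dest) {
  utils::write.csv(layer, dest, row.names = FALSE, quote = FALSE)
  invisible(dest)
}

#' Read / write a peak list
#'
#' Peak lists are `sample_id,rt,irm,intensity,method` CSVs, one row per
#' detected peak.
#'
#' @param source,dest file path.
#' @param peaks data.frame of peaks.
#' @return `read_peaks`: data.frame of peaks; `write_peaks`: `dest`,
#'   invisibly.
#' @export
read_peaks <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("sample_id", "rt", "irm", "intensity", "method")
  if (!all(need %in% names(df))) {
    stop("peak list must have columns ", paste(need, collapse = ","))
  }
  df[, need, drop = FALSE]
}

#' @rdname read_peaks
#' @export
write_peaks <- function(peaks, dest) {
  header <- "sample_id,rt,irm,intensity,method"
  rows <- if (nrow(peaks)) {
    paste(peaks$sample_id, fmt_num(peaks$rt), fmt_num(peaks$irm),
          fmt_num(peaks$intensity), peaks$method, sep = ",")
  } else character(0)
  writeLines(c(header, rows), dest, useBytes = TRUE)
  invisible(dest)
}
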