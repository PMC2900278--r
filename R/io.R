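#' Read and write tab-delimited expression, measurement, and design matrices
#'
#' All matrices travel as UTF-8 tab-delimited text with "." as the decimal
#' separator: an optional leading comment line `# scale=linear|log2`, a
#' header row of column labels, and one row per gene (or pool, for designs)
#' whose first field is its identifier. Values round-trip at full double
#' precision.
#'
#' Expression and measurement files without a scale comment are treated as
#' log2 with a warning, matching the convention of published log-transformed
#' supplementary matrices. Design files are binary and carry no scale line.
#'
#' @param path file path.
#' @param kind what the file holds: `"expression"` (genes x samples),
#'   `"measurement"` (genes x pools), or `"design"` (pools x samples,
#'   binary).
#' @return For `"design"`, a [pooling_design]; otherwise a numeric matrix
#'   with dimnames and a `"scale"` attribute.
#' @export
read_matrix <- function(path, kind = c("expression", "measurement", "design")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop_("%s: empty file", path)
  meta <- character(0)
  first_data <- 1L
  while (first_data <= length(lines) && startsWith(lines[first_data], "#")) {
    meta <- c(meta, lines[first_data])
    first_data <- first_data + 1L
  }
  if (first_data > length(lines)) stop_("%s: no header row after comments", path)
  scale <- NA_character_
  for (m in meta) {
    kv <- regmatches(m, regexec("scale\\s*=\\s*(linear|log2)", m))[[1L]]
    if (length(kv) == 2L) scale <- kv[2L]
  }
  header <- strsplit(lines[first_data], "\t", fixed = TRUE)[[1L]]
  n_col <- length(header) - 1L
  if (n_col < 1L) stop_("%s: header row needs an id column plus data columns", path)
  col_labels <- header[-1L]
  data_lines <- lines[-seq_len(first_data)]
  data_lines <- data_lines[nzchar(data_lines)]
  if (!length(data_lines)) stop_("%s: no data rows", path)
  ids <- character(length(data_lines))
  vals <- matrix(NA_real_, length(data_lines), n_col)
  for (i in seq_along(data_lines)) {
    line_no <- first_data + i # header is line first_data; data starts after
    fields <- strsplit(data_lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != n_col + 1L) {
      stop_("%s: line %d has %d fields, expected %d (ragged row)",
            path, line_no, length(fields), n_col + 1L)
    }
    ids[i] <- fields[1L]
    v <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop_("%s: line %d, column %d: non-numeric cell '%s'",
            path, line_no, bad + 1L, fields[bad + 1L])
    }
    vals[i, ] <- v
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop_("%s: duplicate row identifiers: %s", path,
          paste(unique(dup), collapse = ", "))
  }
  dimnames(vals) <- list(ids, col_labels)
  if (kind == "design") {
    if (!all(vals %in% c(0, 1))) {
      stop_("%s: design cells must all be 0 or 1", path)
    }
    storage.mode(vals) <- "integer"
    cs <- colSums(vals)
    if (length(unique(cs)) != 1L) {
      stop_("%s: design columns must share one left degree; column sums vary", path)
    }
    return(validate_design(new_pooling_design(vals, left_degree = cs[1L])))
  }
  if (is.na(scale)) {
    warning(sprintf("%s: no '# scale=' header; assuming log2", path), call. = FALSE)
    scale <- "log2"
  }
  if (scale == "linear" && any(vals < 0)) {
    stop_("%s: linear-scale intensities must be nonnegative", path)
  }
  attr(vals, "scale") <- scale
  vals
}

#' @rdname read_matrix
#' @param x numeric matrix (genes as rows) to write.
#' @param scale scale recorded in the file header.
#' @export
write_matrix <- function(x, path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (is.data.frame(x)) x <- as.matrix(x)
  stopifnot(is.matrix(x), is.numeric(x))
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(x)))
  cols <- colnames(x)
  if (is.null(cols)) cols <- paste0("c", seq_len(ncol(x)))
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(ids[i], sprintf("%.17g", x[i, ])), collapse = "\t")
  }, character(1))
  writeLines(
    c(sprintf("# scale=%s", scale),
      paste(c("id", cols), collapse = "\t"),
      body),
    path, useBytes = TRUE
  )
  invisible(path)
}

#' @rdname read_matrix
#' @param design a [pooling_design] to write.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "pooling_design"))
  m <- design$matrix
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], m[i, ]), collapse = "\t")
  }, character(1))
  writeLines(
    c(paste(c("pool", colnames(m)), collapse = "\t"), body),
    path, useBytes = TRUE
  )
  invisible(path)
}

#' @rdname read_matrix
#' @export
read_design <- function(path) {
  read_matrix(path, kind = "design")
}

#' Read a simulation configuration from JSON or YAML
#'
#' Fields are passed straight to [simulation_config()]; unknown fields are an
#' error so typos never pass silently.
#'
#' @param path path to a `.json`, `.yaml`, or `.yml` file.
#' @return A validated [simulation_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop_("config must be .json, .yaml, or .yml: %s", path)
  }
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop_("unknown simulation config fields: %s", paste(unknown, collapse = ", "))
  }
  do.call(simulation_config, cfg)
}
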