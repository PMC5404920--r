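# Validated readers/writers for the pipeline's tables.  CSV dialect:
# comma-separated, UTF-8, '.' decimal, mandatory header.  Synthetic
# tables travel with a JSON metadata sidecar holding the ground truth.

table_schemas <- list(
  first_binding = list(
    cols = c(t_bind = "numeric", position_nm = "numeric", age_s = "numeric",
             filament_length_nm = "numeric", censored = "logical"),
    check = function(d) {
      bad <- which(!d$censored &
                     (d$t_bind < 0 | d$position_nm < 0 |
                        d$position_nm > d$filament_length_nm + 1e-9))
      if (length(bad)) sprintf("binding position outside filament in row(s) %s",
                               paste(head(bad, 5), collapse = ", "))
    }
  ),
  second_binding = list(
    cols = c(La = "numeric", L1 = "numeric", x1 = "numeric", L2 = "numeric",
             overlapped = "logical"),
    optional = "overlapped",
    check = function(d) {
      tryCatch({ second_binding_events(d); NULL },
               error = function(e) conditionMessage(e))
    }
  ),
  residence = list(
    cols = c(duration_s = "numeric", censored = "logical"),
    check = function(d) {
      bad <- which(d$duration_s <= 0)
      if (length(bad)) sprintf("non-positive duration in row(s) %s",
                               paste(head(bad, 5), collapse = ", "))
    }
  ),
  occupancy_curve = list(
    cols = c(concentration = "numeric", occupancy = "numeric"),
    check = function(d) {
      bad <- which(d$occupancy < 0 | d$occupancy > 1 | d$concentration < 0)
      if (length(bad)) sprintf("occupancy outside [0, 1] in row(s) %s",
                               paste(head(bad, 5), collapse = ", "))
    }
  )
)

#' Read or write a validated event table
#'
#' Tables are plain CSV with a mandatory header.  On read, columns are
#' checked against the schema (missing columns, non-numeric cells and
#' invariant violations are reported with row numbers); if a metadata
#' sidecar `<path>.meta.json` exists it is attached as the `truth`
#' attribute.  On write, a synthetic table's ground truth is saved to the
#' sidecar.
#'
#' @param path CSV file path.
#' @param schema One of `"first_binding"`, `"second_binding"`,
#'   `"residence"`, `"occupancy_curve"`.
#' @return A validated tibble (with `truth` attribute when available).
#' @export
read_event_table <- function(path, schema = names(table_schemas)) {
  schema <- match.arg(schema)
  sc <- table_schemas[[schema]]
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- setdiff(names(sc$cols), sc$optional %||% character())
  miss <- setdiff(required, names(d))
  if (length(miss))
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(miss, collapse = ", ")))
  for (col in intersect(names(sc$cols), names(d))) {
    want <- sc$cols[[col]]
    if (want == "numeric") {
      v <- d[[col]]
      if (is.character(v)) v <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(v) & !is.na(d[[col]]))
      if (length(bad))
        abort(sprintf("%s: non-numeric value in column %s, row(s) %s",
                      path, col, paste(head(bad, 5), collapse = ", ")))
      d[[col]] <- v
    } else if (want == "logical") {
      d[[col]] <- as.logical(d[[col]])
      if (anyNA(d[[col]]))
        abort(sprintf("%s: non-logical value in column %s", path, col))
    }
  }
  if (nrow(d) > 0 && !is.null(sc$check)) {
    msg <- sc$check(d)
    if (!is.null(msg)) abort(sprintf("%s: %s", path, msg))
  }
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path))
    attr(d, "truth") <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  d
}

#' @rdname read_event_table
#' @param data The table to write (a `gen_*()` result keeps its truth
#'   metadata).
#' @export
write_event_table <- function(data, path) {
  readr::write_csv(as.data.frame(data), path, progress = FALSE)
  truth <- attr(data, "truth")
  if (!is.null(truth))
    jsonlite::write_json(truth, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a kymograph
#'
#' Writes the intensity matrix as CSV (frames x sites, sentinel -1 beyond
#' the barbed end) and optionally as an 8-bit PGM image (sentinel mapped
#' to 0, levels 0/1/2 stretched to 0-255).
#'
#' @param kymograph A [render_kymograph()] result.
#' @param path Output CSV path.
#' @param pgm Optional PGM path.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymograph, path, pgm = NULL) {
  stopifnot(inherits(kymograph, "kymograph"))
  utils::write.table(kymograph$intensity, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(pgm)) {
    im <- kymograph$intensity
    im[im < 0] <- 0
    im <- round(im / 2 * 255)
    con <- file(pgm, "wb")
    on.exit(close(con))
    writeLines(c("P5", sprintf("%d %d", ncol(im), nrow(im)), "255"), con)
    writeBin(as.integer(t(im)), con, size = 1)
  }
  invisible(path)
}
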