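#' Read one tracing export
#'
#' Reads a single CSV exported after root calling: one row per traced
#' structure, with a structure-label column and a length column (in mm).
#' Exporter column names vary between versions, so both are configurable;
#' matching is case-insensitive. All other columns (root angle, diameter,
#' ...) are carried through unchanged. File metadata (condition, plate, day,
#' genotype, capture date, day-2 seedling number) is parsed from the
#' filename via [parse_filename()].
#'
#' @param path path to the CSV file.
#' @param label_col,length_col names of the structure-label and length
#'   columns (case-insensitive; defaults `"root"` and `"length"`).
#' @param max_seedling passed to the label parser.
#' @return a `tracing_table`: a data.frame with one row per traced structure
#'   and columns `file`, `row`, `label`, `seedling`, `structure`,
#'   `measurable`, `length_mm`, `genotype`, `condition`, `plate`, `day`,
#'   `seedling_image`, `capture_date`, followed by any extra exporter
#'   columns. Attribute `provenance` lists source filenames.
#' @export
read_export <- function(path, label_col = "root", length_col = "length",
                        max_seedling = 24L) {
  if (!file.exists(path)) stop("no such file: ", sQuote(path), call. = FALSE)
  meta <- parse_filename(path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty export file: ", sQuote(path), call. = FALSE)

  find_col <- function(wanted) {
    hit <- which(tolower(names(raw)) == tolower(wanted))
    if (length(hit) == 0L) {
      stop("file ", sQuote(basename(path)), " has no ", sQuote(wanted),
           " column (columns: ", paste(names(raw), collapse = ", "), ")",
           call. = FALSE)
    }
    hit[1L]
  }
  lab_i <- find_col(label_col)
  len_i <- find_col(length_col)

  labels <- as.character(raw[[lab_i]])
  lens <- suppressWarnings(as.numeric(raw[[len_i]]))
  bad_len <- !is.finite(lens) | lens < 0
  if (any(bad_len)) {
    stop("file ", sQuote(basename(path)),
         ": non-numeric, non-finite or negative length in row(s) ",
         paste(which(bad_len), collapse = ", "), call. = FALSE)
  }
  parsed <- tryCatch(
    parse_labels(labels, max_seedling = max_seedling),
    error = function(e) {
      stop("file ", sQuote(basename(path)), ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  key <- tolower(labels)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("file ", sQuote(basename(path)), ": duplicate structure label ",
         sQuote(labels[match(dup, key)]), " in rows ",
         paste(which(key == dup), collapse = ", "), call. = FALSE)
  }
  if (!is.na(meta$seedling_image) &&
      any(parsed$seedling != meta$seedling_image)) {
    warning("file ", sQuote(basename(path)), ": labels for seedling(s) ",
            paste(unique(parsed$seedling[parsed$seedling != meta$seedling_image]),
                  collapse = ", "),
            " in a per-seedling day-2 image named s", meta$seedling_image,
            call. = FALSE)
  }

  out <- data.frame(
    file = basename(path),
    row = seq_len(nrow(raw)),
    label = labels,
    seedling = parsed$seedling,
    structure = parsed$structure,
    measurable = parsed$measurable,
    length_mm = lens,
    genotype = meta$genotype,
    condition = meta$condition,
    plate = meta$plate,
    day = meta$day,
    seedling_image = meta$seedling_image,
    capture_date = meta$capture_date,
    stringsAsFactors = FALSE
  )
  extra <- setdiff(seq_along(raw), c(lab_i, len_i))
  extra <- extra[!tolower(names(raw)[extra]) %in% tolower(names(out))]
  if (length(extra)) out <- cbind(out, raw[extra])
  new_tracing_table(out, provenance = basename(path))
}

new_tracing_table <- function(df, provenance = character()) {
  stopifnot(is.data.frame(df))
  attr(df, "provenance") <- provenance
  class(df) <- c("tracing_table", "data.frame")
  df
}

#' @export
print.tracing_table <- function(x, ...) {
  cat(sprintf(
    "<tracing_table> %d records from %d file(s); condition %s, day(s) %s\n",
    nrow(x), length(attr(x, "provenance")),
    paste(unique(x$condition), collapse = "/"),
    paste(sort(unique(x$day)), collapse = ",")
  ))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Merge the tracing exports of one condition and day
#'
#' Day-0 and day-1 photographs give one export per plate (three files); day-2
#' photographs are taken per seedling (24 files). This merges all exports in
#' a folder (or an explicit vector of paths) into one table, refusing to mix
#' conditions or days, and optionally writes the combined CSV whose name
#' carries the `"(combined)"` marker.
#'
#' @param x a directory containing `.csv` exports, or a character vector of
#'   file paths.
#' @param out where to write the combined CSV: `NULL` (default, nothing
#'   written), `TRUE` (next to the input folder, named
#'   `"<folder name> (combined).csv"`), or an explicit file path.
#' @param ... passed to [read_export()].
#' @return a `tracing_table` containing the union of all records, with
#'   attributes `files_merged` (count) and `combined_path` (if written).
#' @export
merge_exports <- function(x, out = NULL, ...) {
  if (length(x) == 1L && dir.exists(x)) {
    dir <- x
    paths <- list.files(dir, pattern = "\\.csv$", ignore.case = TRUE,
                        full.names = TRUE)
    paths <- paths[!grepl("\\(combined\\)", basename(paths))]
    if (length(paths) == 0L) {
      stop("no .csv exports found in ", sQuote(dir), call. = FALSE)
    }
  } else {
    dir <- NULL
    paths <- x
    if (length(paths) == 0L) stop("no files to merge", call. = FALSE)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("no such file(s): ", paste(sQuote(missing), collapse = ", "),
           call. = FALSE)
    }
  }
  paths <- sort(paths)
  tables <- lapply(paths, read_export, ...)
  conds <- unique(vapply(tables, function(t) t$condition[1L], ""))
  days <- unique(vapply(tables, function(t) t$day[1L], 0L))
  if (length(conds) > 1L || length(days) > 1L) {
    stop("refusing to merge mixed file sets: conditions {",
         paste(conds, collapse = ","), "}, days {",
         paste(days, collapse = ","), "}", call. = FALSE)
  }
  merged <- do.call(rbind, lapply(tables, as.data.frame))
  rownames(merged) <- NULL
  key <- paste(merged$seedling, merged$structure)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (seedling, structure) records across merged files: ",
         paste(dup, collapse = "; "), call. = FALSE)
  }
  merged <- new_tracing_table(
    merged, provenance = unlist(lapply(tables, attr, "provenance"))
  )
  attr(merged, "files_merged") <- length(paths)

  if (!is.null(out) && !identical(out, FALSE)) {
    if (isTRUE(out)) {
      stopifnot(!is.null(dir))
      out <- file.path(dirname(normalizePath(dir)),
                       paste0(basename(normalizePath(dir)), " (combined).csv"))
    }
    write_combined(merged, out)
    attr(merged, "combined_path") <- out
  }
  merged
}

#' Write a combined tracing CSV
#'
#' Writes the merged table back to the exporter's column layout (`Root`,
#' `Length`, extras) plus a `SourceFile` column recording each record's
#' original export, so [read_combined()] can reconstruct the full table.
#'
#' @param table a `tracing_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_combined <- function(table, path) {
  stopifnot(inherits(table, "tracing_table"))
  core <- c("file", "row", "label", "seedling", "structure", "measurable",
            "length_mm", "genotype", "condition", "plate", "day",
            "seedling_image", "capture_date")
  extras <- setdiff(names(table), core)
  out <- data.frame(Root = table$label, Length = table$length_mm,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (length(extras)) out <- cbind(out, as.data.frame(table)[extras])
  out$SourceFile <- table$file
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a combined tracing CSV back
#'
#' Inverse of [write_combined()]: each row's metadata is re-parsed from its
#' `SourceFile` column (combined filenames themselves carry no plate token).
#'
#' @param path path to a `"(combined)"` CSV.
#' @param max_seedling passed to the label parser.
#' @return a `tracing_table`.
#' @export
read_combined <- function(path, max_seedling = 24L) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"SourceFile" %in% names(raw)) {
    stop("not a combined CSV (no SourceFile column): ", sQuote(path),
         call. = FALSE)
  }
  parsed <- parse_labels(raw$Root, max_seedling = max_seedling)
  metas <- lapply(raw$SourceFile, parse_filename)
  out <- data.frame(
    file = raw$SourceFile,
    row = seq_len(nrow(raw)),
    label = raw$Root,
    seedling = parsed$seedling,
    structure = parsed$structure,
    measurable = parsed$measurable,
    length_mm = as.numeric(raw$Length),
    genotype = vapply(metas, `[[`, "", "genotype"),
    condition = vapply(metas, `[[`, "", "condition"),
    plate = vapply(metas, `[[`, 0L, "plate"),
    day = vapply(metas, `[[`, 0L, "day"),
    seedling_image = vapply(metas, `[[`, NA_integer_, "seedling_image"),
    capture_date = as.Date(vapply(metas, function(m) as.character(m$capture_date), "")),
    stringsAsFactors = FALSE
  )
  extras <- setdiff(names(raw), c("Root", "Length", "SourceFile"))
  if (length(extras)) out <- cbind(out, raw[extras])
  new_tracing_table(out, provenance = unique(raw$SourceFile))
}
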