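#' Parse a traced-structure label
#'
#' Structure labels identify which organ of which seedling a tracing belongs
#' to. The grammar accepts `seed<i>rt<k>` or `seed<i>r<k>` for root `k` of
#' seedling `i`, and `seed<i>sht` or `seed<i>st` for the shoot (coleoptile),
#' case-insensitively. A trailing `_NA` marks a late root (4-6) that is
#' present but not fully visible against the plate wall, hence not
#' measurable; roots 1-3 and the shoot are never marked `_NA` because a
#' missing tracing already encodes their occlusion.
#'
#' The grammar is deliberately whitespace-intolerant: labels are hand-typed
#' during root calling and strict parsing surfaces typos early.
#'
#' @param text a single label string, e.g. `"seed1rt1"`.
#' @param max_seedling largest admissible seedling index (default 24, the
#'   full two-row-of-four times three-plate design).
#' @return an object of class `structure_label`: a list with elements
#'   `seedling` (integer), `kind` (`"root"` or `"shoot"`), `root_number`
#'   (integer or `NA`), `measurable` (logical) and `structure` (canonical
#'   name, e.g. `"root4"` or `"shoot"`).
#' @examples
#' parse_structure_label("seed1rt1")
#' parse_structure_label("seed24sht")
#' parse_structure_label("seed1r4_NA")
#' @export
parse_structure_label <- function(text, max_seedling = 24L) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("structure label must be a single non-empty string", call. = FALSE)
  }
  df <- parse_labels(text, max_seedling = max_seedling)
  out <- list(
    seedling = df$seedling[1L],
    kind = df$kind[1L],
    root_number = df$root_number[1L],
    measurable = df$measurable[1L],
    structure = df$structure[1L]
  )
  class(out) <- "structure_label"
  out
}

#' @export
print.structure_label <- function(x, ...) {
  cat(sprintf(
    "<structure_label> seedling %d, %s%s\n", x$seedling, x$structure,
    if (!x$measurable) " (not measurable)" else ""
  ))
  invisible(x)
}

# Vectorised label parser shared by read_export(); errors name the offending
# token. Returns a data.frame(seedling, kind, root_number, measurable,
# structure).
parse_labels <- function(labels, max_seedling = 24L) {
  lab <- tolower(labels)
  m <- regmatches(lab, regexec("^seed([0-9]+)(rt|r|sht|st)([0-9]*)(_na)?$", lab))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed structure label(s): ",
         paste(sQuote(labels[bad]), collapse = ", "), call. = FALSE)
  }
  seedling <- as.integer(vapply(m, `[`, "", 2L))
  kind_tok <- vapply(m, `[`, "", 3L)
  num_tok <- vapply(m, `[`, "", 4L)
  na_tok <- vapply(m, `[`, "", 5L)

  is_shoot <- kind_tok %in% c("sht", "st")
  if (any(is_shoot & nzchar(num_tok))) {
    stop("malformed structure label(s): shoot with a root number: ",
         paste(sQuote(labels[is_shoot & nzchar(num_tok)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is_shoot & !nzchar(num_tok))) {
    stop("malformed structure label(s): root without a root number: ",
         paste(sQuote(labels[!is_shoot & !nzchar(num_tok)]), collapse = ", "),
         call. = FALSE)
  }
  root_number <- rep(NA_integer_, length(lab))
  root_number[!is_shoot] <- as.integer(num_tok[!is_shoot])

  if (any(seedling < 1L)) {
    stop("seedling index must be >= 1 in label(s): ",
         paste(sQuote(labels[seedling < 1L]), collapse = ", "), call. = FALSE)
  }
  if (any(seedling > max_seedling)) {
    stop("seedling index exceeds ", max_seedling, " in label(s): ",
         paste(sQuote(labels[seedling > max_seedling]), collapse = ", "),
         call. = FALSE)
  }
  bad_root <- !is_shoot & (root_number < 1L | root_number > 6L)
  if (any(bad_root)) {
    stop("root number must be in 1-6 in label(s): ",
         paste(sQuote(labels[bad_root]), collapse = ", "), call. = FALSE)
  }
  measurable <- !nzchar(na_tok)
  # _NA distinguishes present-but-hidden from not-yet-emerged, which only
  # applies to late roots; earlier structures exist from day 0.
  bad_na <- !measurable & (is_shoot | root_number < 4L)
  if (any(bad_na)) {
    stop("'_NA' is only allowed on roots 4-6, offending label(s): ",
         paste(sQuote(labels[bad_na]), collapse = ", "), call. = FALSE)
  }
  data.frame(
    seedling = seedling,
    kind = ifelse(is_shoot, "shoot", "root"),
    root_number = root_number,
    measurable = measurable,
    structure = ifelse(is_shoot, "shoot", paste0("root", root_number)),
    stringsAsFactors = FALSE
  )
}

#' Parse an export filename into file metadata
#'
#' Filenames follow the plate-photography scheme
#' `"20160413 Zak wt WW1 day0.csv"`: a leading capture date (`YYYYMMDD`,
#' optional), the cultivar/genotype as the token after the first space, a
#' condition+plate token (`WW1`-`WW3`, `WS1`-`WS3`), a `day0|day1|day2` token,
#' and, for day-2 per-seedling photographs only, a seedling token `s1`-`s24`.
#' Any other tokens (such as `"wt"` in the example) are free text and ignored.
#'
#' @param name a filename (path components and case of the `.csv` extension
#'   are ignored).
#' @return an object of class `file_meta`: list with `capture_date` (`Date`
#'   or `NA`), `genotype`, `condition` (`"WW"` or `"WS"`), `plate` (integer
#'   1-3), `day` (integer 0-2) and `seedling_image` (integer or `NA`).
#' @examples
#' parse_filename("20160413 Zak wt WW1 day0.csv")
#' parse_filename("20160415 Zak wt WS3 day2 s24.csv")
#' @export
parse_filename <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    stop("filename must be a single string", call. = FALSE)
  }
  base <- basename(name)
  if (!grepl("\\.csv$", base, ignore.case = TRUE)) {
    stop("not a .csv filename: ", sQuote(base), call. = FALSE)
  }
  stem <- sub("\\.csv$", "", base, ignore.case = TRUE)
  tokens <- strsplit(stem, " +")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  lower <- tolower(tokens)

  cond_idx <- grep("^(ww|ws)[1-3]$", lower)
  if (length(cond_idx) == 0L) {
    stop("no condition/plate token (WW1-3 or WS1-3) in filename ",
         sQuote(base), call. = FALSE)
  }
  if (length(cond_idx) > 1L) {
    stop("multiple condition/plate tokens in filename ", sQuote(base),
         call. = FALSE)
  }
  day_idx <- grep("^day[0-2]$", lower)
  if (length(day_idx) != 1L) {
    stop("expected exactly one day0/day1/day2 token in filename ",
         sQuote(base), call. = FALSE)
  }
  condition <- toupper(substr(tokens[cond_idx], 1L, 2L))
  plate <- as.integer(substr(tokens[cond_idx], 3L, 3L))
  day <- as.integer(sub("^day", "", lower[day_idx]))

  seed_idx <- grep("^s([1-9]|1[0-9]|2[0-4])$", lower)
  seedling_image <- NA_integer_
  if (length(seed_idx) > 1L) {
    stop("multiple seedling tokens in filename ", sQuote(base), call. = FALSE)
  }
  if (length(seed_idx) == 1L) {
    if (day != 2L) {
      stop("seedling token ", sQuote(tokens[seed_idx]),
           " only permitted on day-2 filenames: ", sQuote(base), call. = FALSE)
    }
    seedling_image <- as.integer(sub("^s", "", lower[seed_idx]))
  }

  capture_date <- as.Date(NA)
  if (grepl("^[0-9]{8}$", tokens[1L])) {
    capture_date <- as.Date(tokens[1L], format = "%Y%m%d")
  }
  genotype <- NA_character_
  if (length(tokens) >= 2L && !(2L %in% c(cond_idx, day_idx, seed_idx))) {
    genotype <- tokens[2L]
  }

  out <- list(
    capture_date = capture_date, genotype = genotype, condition = condition,
    plate = plate, day = day, seedling_image = seedling_image
  )
  class(out) <- "file_meta"
  out
}

#' @export
print.file_meta <- function(x, ...) {
  cat(sprintf(
    "<file_meta> %s plate %d, day %d, genotype %s%s%s\n",
    x$condition, x$plate, x$day, x$genotype,
    if (!is.na(x$seedling_image)) sprintf(", seedling %d", x$seedling_image) else "",
    if (!is.na(x$capture_date)) sprintf(", %s", format(x$capture_date)) else ""
  ))
  invisible(x)
}
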