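#' Compile one condition's three-day time course
#'
#' Turns the merged day-0, day-1 and day-2 tables of a single condition into
#' a complete seedling x structure x day long table with explicit
#' replicate-accounting semantics:
#'
#' * a tracing present and measurable is `measured`;
#' * a tracing labelled `_NA` (present but not fully visible) is `occluded`
#'   and excluded from means and from `n` for that structure/day only;
#' * roots 1-3 and the shoot exist from day 0, so a *missing* tracing for
#'   them means the photograph hid them: `occluded`;
#' * roots 4-6 emerge late, so a missing tracing means the root has not yet
#'   appeared: `absent`, scored as length 0 and counted toward `n`;
#' * a seedling with no tracings at all on a day is treated as a missing
#'   photograph: every one of its structures is `occluded` that day.
#'
#' Day-0 and day-2 photographs are expected complete (day 2 is photographed
#' per seedling), so missing early structures there raise a warning. A late
#' root measured with positive length on one day but missing on a later day
#' is contradictory (an emerged root cannot un-emerge) and is an error.
#' Measured lengths that decrease across days are flagged with a warning but
#' kept: on real tracings they reveal calling errors and must stay visible.
#'
#' @param day0,day1,day2 `tracing_table`s (typically from [merge_exports()])
#'   sharing one condition and genotype.
#' @return a `compiled_condition`: data.frame with columns `genotype`,
#'   `condition`, `plate`, `seedling`, `structure`, `day`, `length_mm`
#'   (`NA` when occluded, 0 when absent) and `status`. One row per seedling,
#'   structure and day. Attributes: `n_seedlings`, `structures`,
#'   `root6_evidence` (seedling indices with direct evidence of a sixth
#'   root).
#' @export
compile_condition <- function(day0, day1, day2) {
  tabs <- list(day0, day1, day2)
  for (d in 1:3) {
    t <- tabs[[d]]
    if (!inherits(t, "tracing_table")) {
      stop("day", d - 1L, " input is not a tracing_table", call. = FALSE)
    }
    if (!all(t$day == d - 1L)) {
      stop("day", d - 1L, " input contains records for day(s) ",
           paste(unique(t$day), collapse = ","), call. = FALSE)
    }
  }
  conds <- unique(unlist(lapply(tabs, function(t) t$condition)))
  if (length(conds) != 1L) {
    stop("inputs mix conditions: ", paste(conds, collapse = ", "), call. = FALSE)
  }
  genos <- unique(unlist(lapply(tabs, function(t) t$genotype)))
  genos <- genos[!is.na(genos)]
  if (length(genos) > 1L) {
    stop("inputs mix genotypes: ", paste(genos, collapse = ", "), call. = FALSE)
  }
  genotype <- if (length(genos)) genos else NA_character_

  d0 <- as.data.frame(day0)
  plate_map <- tapply(d0$plate, d0$seedling, function(p) unique(p))
  if (any(lengths(plate_map) != 1L)) {
    stop("seedling(s) appear on more than one plate at day 0: ",
         paste(names(plate_map)[lengths(plate_map) != 1L], collapse = ", "),
         call. = FALSE)
  }
  seedlings <- sort(as.integer(names(plate_map)))
  plate_of <- stats::setNames(vapply(plate_map, `[`, 0L, 1L), names(plate_map))

  for (d in 2:3) {
    t <- tabs[[d]]
    unknown <- setdiff(unique(t$seedling), seedlings)
    if (length(unknown)) {
      stop("day", d - 1L, " has unknown seedling index(es) ",
           paste(unknown, collapse = ", "),
           " not present at day 0", call. = FALSE)
    }
    moved <- t$seedling[!is.na(t$plate) &
                          t$plate != plate_of[as.character(t$seedling)]]
    if (length(moved)) {
      stop("seedling(s) ", paste(unique(moved), collapse = ", "),
           " recorded on a different plate on day ", d - 1L,
           " than on day 0", call. = FALSE)
    }
  }

  has_root6 <- any(vapply(tabs, function(t) any(t$structure == "root6"), TRUE))
  structures <- c("shoot", paste0("root", 1:5), if (has_root6) "root6")
  late <- c("root4", "root5", "root6")

  grid <- expand.grid(
    seedling = seedlings, structure = structures, day = 0:2,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$plate <- plate_of[as.character(grid$seedling)]
  grid$length_mm <- NA_real_
  grid$status <- NA_character_

  warn_missing_early <- character()
  for (d in 1:3) {
    t <- as.data.frame(tabs[[d]])
    gsel <- grid$day == d - 1L
    gkey <- paste(grid$seedling[gsel], grid$structure[gsel])
    tkey <- paste(t$seedling, t$structure)
    hit <- match(gkey, tkey)
    status <- ifelse(!is.na(hit),
                     ifelse(t$measurable[hit], "measured", "occluded"),
                     NA)
    length_mm <- ifelse(!is.na(hit) & t$measurable[hit],
                        t$length_mm[hit], NA_real_)
    miss <- is.na(hit)
    seed_absent <- !(grid$seedling[gsel] %in% t$seedling)
    status[miss & seed_absent] <- "occluded"  # missing photograph
    is_late <- grid$structure[gsel] %in% late
    status[miss & !seed_absent & is_late] <- "absent"
    length_mm[miss & !seed_absent & is_late] <- 0
    status[miss & !seed_absent & !is_late] <- "occluded"
    if (d %in% c(1L, 3L)) {
      off <- miss & !is_late
      if (any(off)) {
        warn_missing_early <- c(warn_missing_early, sprintf(
          "day %d: %s of seedling %d", d - 1L,
          grid$structure[gsel][off], grid$seedling[gsel][off]
        ))
      }
    }
    grid$status[gsel] <- status
    grid$length_mm[gsel] <- length_mm
  }
  if (length(warn_missing_early)) {
    warning("structures expected visible are missing from day-0/day-2 ",
            "photographs (treated as occluded): ",
            paste(warn_missing_early, collapse = "; "), call. = FALSE)
  }

  # an emerged late root cannot go back to absent
  key <- paste(grid$seedling, grid$structure)
  for (k in unique(key[grid$structure %in% late])) {
    rows <- grid[key == k, ]
    rows <- rows[order(rows$day), ]
    emerged_day <- rows$day[rows$status == "measured" & rows$length_mm > 0]
    if (length(emerged_day) &&
        any(rows$status == "absent" & rows$day > min(emerged_day))) {
      stop("inconsistent records: ", rows$structure[1L], " of seedling ",
           rows$seedling[1L], " measured on day ", min(emerged_day),
           " but missing (scored absent) on a later day", call. = FALSE)
    }
  }

  # shrinking measured lengths flag tracing errors but are not rejected
  shrunk <- character()
  for (k in unique(key)) {
    rows <- grid[key == k & grid$status == "measured", ]
    if (nrow(rows) >= 2L) {
      rows <- rows[order(rows$day), ]
      if (any(diff(rows$length_mm) < 0)) {
        shrunk <- c(shrunk, sprintf("%s of seedling %d", rows$structure[1L],
                                    rows$seedling[1L]))
      }
    }
  }
  if (length(shrunk)) {
    warning("measured length decreases across days for: ",
            paste(shrunk, collapse = "; "), call. = FALSE)
  }

  out <- data.frame(
    genotype = genotype, condition = conds, plate = unname(grid$plate),
    seedling = grid$seedling, structure = grid$structure, day = grid$day,
    length_mm = grid$length_mm, status = grid$status,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$seedling, match(out$structure, structures), out$day), ]
  rownames(out) <- NULL

  # direct evidence of a sixth root: a measured positive length or an _NA
  # tracing (present but hidden); a missing day-1 photograph is not evidence
  ev <- integer()
  for (d in 1:3) {
    t <- as.data.frame(tabs[[d]])
    r6 <- t[t$structure == "root6" & (!t$measurable | t$length_mm > 0), ]
    ev <- union(ev, r6$seedling)
  }
  new_compiled_condition(out, n_seedlings = length(seedlings),
                         structures = structures,
                         root6_evidence = sort(ev))
}

new_compiled_condition <- function(df, n_seedlings, structures,
                                   root6_evidence = integer()) {
  attr(df, "n_seedlings") <- n_seedlings
  attr(df, "structures") <- structures
  attr(df, "root6_evidence") <- root6_evidence
  class(df) <- c("compiled_condition", "data.frame")
  df
}

#' @export
print.compiled_condition <- function(x, ...) {
  cat(sprintf(
    "<compiled_condition> %s, %s: %d seedlings x %d structures x 3 days\n",
    x$genotype[1L], x$condition[1L], attr(x, "n_seedlings"),
    length(attr(x, "structures"))
  ))
  tab <- table(x$status)
  cat("  status counts:",
      paste(names(tab), unclass(tab), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Mean length of one structure on one day
#'
#' Means average over `measured` and `absent` rows: an occluded root drops
#' out of both the mean and `n` for that structure/day, while a not-yet
#' emerged late root enters as a true zero and counts toward `n`.
#'
#' @param compiled a `compiled_condition`.
#' @param structure structure name (`"shoot"`, `"root1"`..`"root6"`).
#' @param day 0, 1 or 2.
#' @return list with `mean_mm` (`NA` when every replicate is occluded) and
#'   `n`.
#' @export
structure_mean <- function(compiled, structure, day) {
  stopifnot(inherits(compiled, "compiled_condition"))
  rows <- compiled[compiled$structure == structure & compiled$day == day, ]
  if (nrow(rows) == 0L) {
    stop("no rows for structure ", sQuote(structure), " on day ", day,
         call. = FALSE)
  }
  use <- rows$status != "occluded"
  n <- sum(use)
  list(mean_mm = if (n > 0L) mean(rows$length_mm[use]) else NA_real_, n = n)
}

#' Decide whether a sixth root is analysed
#'
#' Some wheat varieties carry a sixth seminal root. It is ignored in plots
#' and summaries unless strictly more than `threshold` of the condition's
#' seedlings show direct evidence of one (a measured positive length or a
#' present-but-hidden `_NA` tracing on any day).
#'
#' @param compiled a `compiled_condition`.
#' @param threshold inclusion cutoff (default 3; strict `>`).
#' @return `TRUE` if root 6 should appear in plots, summaries and statistics.
#' @export
root6_included <- function(compiled, threshold = 3L) {
  stopifnot(inherits(compiled, "compiled_condition"))
  ev <- attr(compiled, "root6_evidence")
  if (is.null(ev)) {
    r6 <- compiled[compiled$structure == "root6", ]
    ev <- unique(r6$seedling[r6$status == "occluded" |
                               (r6$status == "measured" & r6$length_mm > 0)])
  }
  length(ev) > threshold
}

#' Mean growth increments between consecutive time points
#'
#' For each structure and interval (day 0 to 1, day 1 to 2), averages the
#' per-seedling length change over seedlings usable at *both* endpoints
#' (measured or absent; an occluded endpoint drops the seedling from that
#' interval only). Negative increments are kept, with a warning, since they
#' indicate tracing errors worth seeing.
#'
#' @param compiled a `compiled_condition`.
#' @return a data.frame of class `growth_segments` with columns `structure`,
#'   `interval` (`"day0_1"`, `"day1_2"`), `mean_change_mm` and `n`.
#' @export
growth_increments <- function(compiled) {
  stopifnot(inherits(compiled, "compiled_condition"))
  structures <- attr(compiled, "structures")
  res <- list()
  any_negative <- FALSE
  for (s in structures) {
    sub <- compiled[compiled$structure == s, ]
    wide <- stats::reshape(
      sub[, c("seedling", "day", "length_mm", "status")],
      direction = "wide", idvar = "seedling", timevar = "day"
    )
    for (iv in list(c(0L, 1L), c(1L, 2L))) {
      st_a <- wide[[paste0("status.", iv[1L])]]
      st_b <- wide[[paste0("status.", iv[2L])]]
      ok <- st_a != "occluded" & st_b != "occluded"
      delta <- wide[[paste0("length_mm.", iv[2L])]][ok] -
        wide[[paste0("length_mm.", iv[1L])]][ok]
      if (length(delta) && any(delta < 0)) any_negative <- TRUE
      res[[length(res) + 1L]] <- data.frame(
        structure = s, interval = paste0("day", iv[1L], "_", iv[2L]),
        mean_change_mm = if (length(delta)) mean(delta) else NA_real_,
        n = length(delta), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  if (any_negative) {
    warning("negative growth increments present (kept; check tracings)",
            call. = FALSE)
  }
  class(out) <- c("growth_segments", "data.frame")
  out
}

#' Export a compiled condition as long-format CSV
#'
#' @param compiled a `compiled_condition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_compiled <- function(compiled, path) {
  stopifnot(inherits(compiled, "compiled_condition"))
  utils::write.csv(as.data.frame(compiled), path, row.names = FALSE)
  invisible(path)
}
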