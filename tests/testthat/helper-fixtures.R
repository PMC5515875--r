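# Fixture builders and independent oracles shared across the suite.
# All fixtures are generated in code at test time; nothing is stored on disk.

# Write one tracing export CSV with the experiment's filename scheme.
# rows: data.frame with columns Root and Length (extras allowed).
write_export_csv <- function(dir, condition, plate, day, rows,
                             genotype = "Zak", seedling = NULL) {
  date <- format(as.Date("2016-04-13") + day, "%Y%m%d")
  fn <- if (is.null(seedling)) {
    sprintf("%s %s wt %s%d day%d.csv", date, genotype, condition, plate, day)
  } else {
    sprintf("%s %s wt %s%d day%d s%d.csv", date, genotype, condition, plate,
            day, seedling)
  }
  path <- file.path(dir, fn)
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

# Build a merged tracing_table for one condition and day from a list of
# per-plate record data.frames (exercises the real CSV path end to end).
make_day_table <- function(condition, day, plates, dir = NULL) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- vapply(
    seq_along(plates),
    function(i) write_export_csv(dir, condition, i, day, plates[[i]]),
    ""
  )
  merge_exports(paths)
}

rows_of <- function(labels, lengths) {
  data.frame(Root = labels, Length = lengths, stringsAsFactors = FALSE)
}

# Compiled condition with zero plate and zero seedling variance: every cell
# (condition x day) holds the same balanced set of offsets around its mean,
# rotated across days so no seedling carries a persistent effect and every
# plate's offsets sum to zero. delta: per-day WS - WW shift (length 3).
zero_variance_conditions <- function(delta = c(0, 0, 0),
                                     base = c(10, 20, 30),
                                     n_per_plate = 4L, n_plates = 2L) {
  pattern <- rep(c(-0.75, -0.25, 0.25, 0.75), length.out = n_per_plate * n_plates)
  n <- length(pattern)
  build <- function(condition, shift) {
    tabs <- lapply(0:2, function(d) {
      offs <- pattern[((seq_len(n) - 1L + d) %% n) + 1L]
      vals <- base[d + 1L] + shift[d + 1L] + offs
      plates <- lapply(seq_len(n_plates), function(p) {
        idx <- ((p - 1L) * n_per_plate + 1L):(p * n_per_plate)
        rows_of(paste0("seed", idx, "rt1"), vals[idx])
      })
      make_day_table(condition, d, plates, dir = withr::local_tempdir())
    })
    # only root 1 is traced in this fixture; silence the completeness warning
    suppressWarnings(compile_condition(tabs[[1]], tabs[[2]], tabs[[3]]))
  }
  list(
    ww = build("WW", c(0, 0, 0)),
    ws = build("WS", delta),
    values = function(condition, d) {
      offs <- pattern[((seq_len(n) - 1L + d) %% n) + 1L]
      base[d + 1L] + (if (condition == "WS") delta[d + 1L] else 0) + offs
    }
  )
}

# Brute-force replicate-accounting oracle: recompute a structure/day mean
# and n by direct enumeration over the raw per-day records, independently of
# compile_condition's implementation.
oracle_mean <- function(day_tables, seedlings, structure, day) {
  t <- as.data.frame(day_tables[[day + 1L]])
  late <- structure %in% c("root4", "root5", "root6")
  vals <- numeric()
  for (s in seedlings) {
    if (!s %in% t$seedling) next                      # photo missing: occluded
    r <- t[t$seedling == s & t$structure == structure, ]
    if (nrow(r) == 1L) {
      if (r$measurable) vals <- c(vals, r$length_mm)  # measured
      # else _NA tracing: occluded, skip
    } else if (late) {
      vals <- c(vals, 0)                              # not yet emerged
    }                                                 # else occluded, skip
  }
  list(mean = if (length(vals)) mean(vals) else NA_real_, n = length(vals))
}

# Compile both conditions of an in-memory simulated experiment.
compile_sim <- function(sim) {
  list(
    ww = compile_condition(sim$ww$day0, sim$ww$day1, sim$ww$day2),
    ws = compile_condition(sim$ws$day0, sim$ws$day1, sim$ws$day2)
  )
}

# Rigid motion of a polyline: rotate by theta, then translate.
rigid_motion <- function(p, theta, dx, dy) {
  r <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  sweep(p %*% r, 2L, c(dx, dy), "+")
}

# Raw PDF bytes with the timestamp dictionary entries blanked, so renders
# can be compared for byte-determinism.
pdf_payload <- function(path) {
  b <- readBin(path, "raw", file.size(path))
  orig <- b
  close_paren <- charToRaw(")")
  for (pat in c("/CreationDate", "/ModDate")) {
    p <- charToRaw(pat)
    hits <- which(orig == p[1L])
    for (h in hits) {
      if (h + length(p) - 1L <= length(orig) &&
          identical(orig[h:(h + length(p) - 1L)], p)) {
        end <- h + length(p)
        while (end <= length(orig) && orig[end] != close_paren) end <- end + 1L
        b[h:min(end, length(b))] <- as.raw(0L)
      }
    }
  }
  b
}
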