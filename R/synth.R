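#' Parameters for the synthetic soil-plate experiment
#'
#' Bundles and validates every knob of the simulated experiment. Defaults
#' mirror the study design the pipeline targets: two conditions (well
#' watered, and water stressed with 20% PEG at about -0.65 MPa), three
#' plates of eight seedlings each per condition (24 replicates), photographs
#' on days 0, 1 and 2 after transplant at 28 degrees C. At transplant the
#' coleoptile (shoot) and roots 1-3 have emerged, root 1 at about 10 mm;
#' roots 4 and 5 emerge later than 24 h after transplant. Growth decelerates
#' between the first and second interval, and water stress inhibits the
#' shoot more strongly than the roots.
#'
#' Growth-rate magnitudes are plausible placeholders for a wheat cultivar at
#' 28 degrees C, not reproductions of any measured trajectory.
#'
#' @param n_plates plates per condition (default 3).
#' @param seedlings_per_plate seedlings per plate (default 8).
#' @param genotype cultivar label used in filenames/tables (default
#'   `"Zak"`).
#' @param start_date capture date of day 0 (used only in filenames).
#' @param baseline_mm named day-0 mean lengths (mm) for structures emerged
#'   at transplant.
#' @param rate01_mm,rate12_mm named mean growth rates (mm/day) over day 0-1
#'   and day 1-2 under WW; late roots use `rate12_mm` from their emergence
#'   time.
#' @param emergence_day named emergence times (days after transplant) for
#'   the late roots; must exceed 1 for roots 4 and 5.
#' @param ws_root_mult,ws_shoot_mult multiplicative effect of water stress
#'   on root and shoot growth rates, in (0, 1]; the shoot multiplier should
#'   be the smaller one (stress inhibits the shoot more).
#' @param root6_prob probability a seedling carries a sixth root (default
#'   0).
#' @param occlusion_prob per-structure probability that a day-1 tracing is
#'   impossible (root grown around the plate edge or away from the wall).
#' @param edge_factor multiplier on `occlusion_prob` for the outward-facing
#'   roots of the outermost seedlings (root 2/4 of the left-most, root 3/5
#'   of the right-most position on a plate).
#' @param noise_sd measurement/growth noise sd in mm, applied to the day-0
#'   length and to each growth increment (truncated so lengths never
#'   shrink).
#' @param plate_sd,seedling_sd sds of Gaussian random intercepts shared by
#'   all structures of a plate / of a seedling.
#' @param psi_w nominal substrate water potentials in MPa (metadata only).
#' @return validated list of class `sim_params`.
#' @export
sim_params <- function(n_plates = 3L,
                       seedlings_per_plate = 8L,
                       genotype = "Zak",
                       start_date = as.Date("2016-04-13"),
                       baseline_mm = c(shoot = 8, root1 = 10, root2 = 8,
                                       root3 = 7),
                       rate01_mm = c(shoot = 10, root1 = 15, root2 = 14,
                                     root3 = 13),
                       rate12_mm = c(shoot = 8, root1 = 12, root2 = 11,
                                     root3 = 10, root4 = 12, root5 = 12,
                                     root6 = 10),
                       emergence_day = c(root4 = 1.25, root5 = 1.5,
                                         root6 = 1.5),
                       ws_root_mult = 0.6,
                       ws_shoot_mult = 0.4,
                       root6_prob = 0,
                       occlusion_prob = 0.05,
                       edge_factor = 2,
                       noise_sd = 0.5,
                       plate_sd = 0.5,
                       seedling_sd = 1.0,
                       psi_w = c(WW = -0.02, WS = -0.65)) {
  p <- list(
    n_plates = as.integer(n_plates),
    seedlings_per_plate = as.integer(seedlings_per_plate),
    genotype = genotype, start_date = as.Date(start_date),
    baseline_mm = baseline_mm, rate01_mm = rate01_mm, rate12_mm = rate12_mm,
    emergence_day = emergence_day,
    ws_root_mult = ws_root_mult, ws_shoot_mult = ws_shoot_mult,
    root6_prob = root6_prob, occlusion_prob = occlusion_prob,
    edge_factor = edge_factor, noise_sd = noise_sd,
    plate_sd = plate_sd, seedling_sd = seedling_sd, psi_w = psi_w
  )
  problems <- character()
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(p$n_plates >= 1L, "n_plates must be >= 1")
  chk(p$seedlings_per_plate >= 1L, "seedlings_per_plate must be >= 1")
  chk(p$n_plates <= 3L, "n_plates above 3 breaks the WW1-WW3 filename grammar")
  chk(all(c("shoot", "root1", "root2", "root3") %in% names(p$baseline_mm)),
      "baseline_mm needs shoot and roots 1-3")
  chk(all(p$baseline_mm >= 0), "baseline_mm must be non-negative")
  chk(all(p$rate01_mm >= 0) && all(p$rate12_mm >= 0), "rates must be >= 0")
  chk(all(c("root4", "root5") %in% names(p$emergence_day)),
      "emergence_day needs root4 and root5")
  chk(all(p$emergence_day[c("root4", "root5")] > 1),
      "roots 4 and 5 emerge later than 24 h after transplant")
  chk(all(p$emergence_day <= 2), "late roots must emerge by day 2")
  chk(p$ws_root_mult > 0 && p$ws_root_mult <= 1,
      "ws_root_mult must be in (0, 1]")
  chk(p$ws_shoot_mult > 0 && p$ws_shoot_mult <= 1,
      "ws_shoot_mult must be in (0, 1]")
  chk(p$root6_prob >= 0 && p$root6_prob <= 1, "root6_prob must be in [0, 1]")
  chk(p$occlusion_prob >= 0 && p$occlusion_prob <= 1,
      "occlusion_prob must be in [0, 1]")
  chk(p$edge_factor >= 1, "edge_factor must be >= 1")
  chk(p$occlusion_prob * p$edge_factor <= 1,
      "occlusion_prob * edge_factor must not exceed 1")
  chk(p$noise_sd >= 0 && p$plate_sd >= 0 && p$seedling_sd >= 0,
      "all sds must be >= 0")
  if (length(problems)) {
    stop("invalid simulation parameters:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> %s: %d plates x %d seedlings x 2 conditions; WS mult root %.2g / shoot %.2g; noise %.2g mm\n",
    x$genotype, x$n_plates, x$seedlings_per_plate,
    x$ws_root_mult, x$ws_shoot_mult, x$noise_sd
  ))
  invisible(x)
}

#' Noise-free expected length trajectory
#'
#' Piecewise-linear mean trajectory for a structure: day-0 baseline plus a
#' first-interval rate and a smaller second-interval rate (growth is fastest
#' between transplant and 24 h), zero before emergence for the late roots.
#' Under water stress every rate is multiplied by the root or shoot
#' multiplier; baselines are shared because both treatments start from the
#' same transplanted seedlings.
#'
#' @param structure `"shoot"` or `"root1"`..`"root6"`.
#' @param condition `"WW"` or `"WS"`.
#' @param day time in days since transplant (may be fractional).
#' @param params a `sim_params`.
#' @return expected length in mm.
#' @export
expected_length <- function(structure, condition, day, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"), day >= 0)
  condition <- match.arg(condition, c("WW", "WS"))
  all_structures <- c("shoot", paste0("root", 1:6))
  if (!structure %in% all_structures) {
    stop("unknown structure ", sQuote(structure), call. = FALSE)
  }
  mult <- if (condition == "WW") 1
  else if (structure == "shoot") params$ws_shoot_mult
  else params$ws_root_mult

  if (structure %in% names(params$emergence_day)) {
    em <- params$emergence_day[[structure]]
    grown <- max(0, day - em)
    return(params$rate12_mm[[structure]] * mult * grown)
  }
  base <- params$baseline_mm[[structure]]
  base +
    params$rate01_mm[[structure]] * mult * min(day, 1) +
    params$rate12_mm[[structure]] * mult * max(0, day - 1)
}

# deterministic global seedling numbering: plate p holds seedlings
# (p-1)*k+1 .. p*k
seedling_plate <- function(seedling, seedlings_per_plate) {
  as.integer((seedling - 1L) %/% seedlings_per_plate + 1L)
}

#' Simulate the full soil-plate experiment
#'
#' Draws plate- and seedling-level Gaussian intercepts shared across a
#' seedling's structures, simulates piecewise-linear growth with additive
#' Gaussian noise on the day-0 length and on each interval's increment
#' (truncated at zero so a structure never shrinks), applies day-1 occlusion
#' (edge-weighted: outward-facing roots of the outermost plate positions
#' are twice as likely to be obscured), and emits the six file sets of the
#' experiment -- per-plate exports on days 0 and 1, per-seedling exports on
#' day 2 -- following the tracing-export filename and label grammar.
#'
#' Occlusion is written exactly as a root caller would: roots 1-3 and the
#' shoot are simply skipped (their absence from the file encodes occlusion),
#' while emerged late roots are written with an `_NA` label suffix. Late
#' roots not yet emerged are omitted entirely (absent, scored 0 downstream).
#'
#' @param params a `sim_params`.
#' @param seed integer RNG seed; identical seeds give identical output,
#'   including byte-identical CSV files.
#' @param out_dir if non-`NULL`, a directory under which the six folders
#'   (`"WW day0"`, ..., `"WS day2"`) of CSV files plus a `params.json`
#'   manifest are written.
#' @return (invisibly when writing) a list with elements `ww` and `ws`,
#'   each a list of `tracing_table`s `day0`, `day1`, `day2`; plus `params`,
#'   `seed`, `truth` (a data.frame of noise-free per-structure seedling
#'   lengths) and, when written, `files`.
#' @export
simulate_experiment <- function(params = sim_params(), seed = 1L,
                                out_dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  seed <- as.integer(seed)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)

  k <- params$seedlings_per_plate
  n_seed <- params$n_plates * k
  early <- c("shoot", "root1", "root2", "root3")
  late <- intersect(c("root4", "root5", "root6"), names(params$emergence_day))

  sim_condition <- function(condition) {
    b_plate <- stats::rnorm(params$n_plates, 0, params$plate_sd)
    b_seed <- stats::rnorm(n_seed, 0, params$seedling_sd)
    has_r6 <- stats::runif(n_seed) < params$root6_prob
    rows <- list()
    for (s in seq_len(n_seed)) {
      plate <- seedling_plate(s, k)
      pos <- (s - 1L) %% k + 1L
      structs <- c(early, "root4", "root5", if (has_r6[s]) "root6")
      for (st in structs) {
        mult <- if (condition == "WW") 1
        else if (st == "shoot") params$ws_shoot_mult
        else params$ws_root_mult
        if (st %in% late) {
          em <- params$emergence_day[[st]]
          rate <- params$rate12_mm[[st]] * mult
          l0 <- 0
          l1 <- if (em <= 1) max(0, rate * (1 - em) +
                                   stats::rnorm(1, 0, params$noise_sd)) else 0
          inc2 <- max(0, rate * (2 - max(em, 1)) +
                        stats::rnorm(1, 0, params$noise_sd))
          l2 <- l1 + inc2
        } else {
          l0 <- max(0, params$baseline_mm[[st]] + b_plate[plate] + b_seed[s] +
                      stats::rnorm(1, 0, params$noise_sd))
          inc1 <- max(0, params$rate01_mm[[st]] * mult +
                        stats::rnorm(1, 0, params$noise_sd))
          inc2 <- max(0, params$rate12_mm[[st]] * mult +
                        stats::rnorm(1, 0, params$noise_sd))
          l1 <- l0 + inc1
          l2 <- l1 + inc2
        }
        # day-1 occlusion, doubled for outward roots at the plate edges
        p_occ <- params$occlusion_prob
        if ((pos == 1L && st %in% c("root2", "root4")) ||
            (pos == k && st %in% c("root3", "root5"))) {
          p_occ <- min(1, p_occ * params$edge_factor)
        }
        occluded1 <- stats::runif(1) < p_occ
        rows[[length(rows) + 1L]] <- data.frame(
          condition = condition, plate = plate, seedling = s, structure = st,
          l0 = l0, l1 = l1, l2 = l2, occluded_day1 = occluded1,
          emerged_day1 = !(st %in% late) ||
            params$emergence_day[[st]] <= 1,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  }

  truth_ww <- sim_condition("WW")
  truth_ws <- sim_condition("WS")
  truth <- rbind(truth_ww, truth_ws)

  build_tables <- function(truth_c, condition) {
    lens <- c("0" = "l0", "1" = "l1", "2" = "l2")
    out <- list()
    for (d in 0:2) {
      recs <- truth_c
      recs$length_mm <- recs[[lens[[as.character(d)]]]]
      if (d < 2L) {
        # pre-emergence late roots are simply not in the photograph
        if (d == 0L) {
          recs <- recs[!(recs$structure %in% late), ]
        } else {
          recs <- recs[recs$emerged_day1 | !(recs$structure %in% late), ]
        }
      }
      recs$measurable <- TRUE
      if (d == 1L) {
        occ <- recs$occluded_day1
        drop_occ <- occ & !(recs$structure %in% late)
        recs$measurable[occ & recs$structure %in% late] <- FALSE
        recs <- recs[!drop_occ, ]
      }
      recs$label <- paste0(
        "seed", recs$seedling,
        ifelse(recs$structure == "shoot", "sht",
               paste0("rt", sub("^root", "", recs$structure))),
        ifelse(recs$measurable, "", "_NA")
      )
      date <- format(params$start_date + d, "%Y%m%d")
      recs$file <- if (d < 2L) {
        sprintf("%s %s wt %s%d day%d.csv", date, params$genotype,
                condition, recs$plate, d)
      } else {
        sprintf("%s %s wt %s%d day%d s%d.csv", date, params$genotype,
                condition, recs$plate, d, recs$seedling)
      }
      tbl <- data.frame(
        file = recs$file,
        row = seq_len(nrow(recs)),
        label = recs$label,
        seedling = recs$seedling,
        structure = recs$structure,
        measurable = recs$measurable,
        length_mm = round(recs$length_mm, 3),
        genotype = params$genotype,
        condition = condition,
        plate = recs$plate,
        day = d,
        seedling_image = if (d == 2L) recs$seedling else NA_integer_,
        capture_date = params$start_date + d,
        stringsAsFactors = FALSE
      )
      tbl <- tbl[order(tbl$file, tbl$seedling,
                       match(tbl$structure, c("shoot", paste0("root", 1:6)))), ]
      tbl$row <- stats::ave(seq_len(nrow(tbl)), tbl$file, FUN = seq_along)
      rownames(tbl) <- NULL
      out[[paste0("day", d)]] <- new_tracing_table(
        tbl, provenance = unique(tbl$file)
      )
    }
    out
  }

  result <- list(
    ww = build_tables(truth_ww, "WW"),
    ws = build_tables(truth_ws, "WS"),
    params = params, seed = seed, truth = truth
  )

  if (!is.null(out_dir)) {
    files <- character()
    for (cond in c("ww", "ws")) {
      for (d in 0:2) {
        tbl <- result[[cond]][[paste0("day", d)]]
        folder <- file.path(out_dir,
                            sprintf("%s day%d", toupper(cond), d))
        dir.create(folder, showWarnings = FALSE, recursive = TRUE)
        for (f in unique(tbl$file)) {
          sub <- tbl[tbl$file == f, ]
          utils::write.csv(
            data.frame(Root = sub$label, Length = sub$length_mm),
            file.path(folder, f), row.names = FALSE
          )
          files <- c(files, file.path(folder, f))
        }
      }
    }
    manifest <- params
    class(manifest) <- NULL
    manifest$start_date <- format(manifest$start_date)
    # keep element names (baseline_mm etc.) in the JSON manifest
    manifest <- lapply(manifest, function(x) {
      if (is.null(names(x))) x else as.list(x)
    })
    jsonlite::write_json(
      c(list(seed = seed), manifest),
      file.path(out_dir, "params.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    result$files <- files
    return(invisible(result))
  }
  result
}

#' Emit synthetic polyline tracings matching simulated lengths
#'
#' For one condition and day of a simulated experiment, writes each traced
#' structure as a polyline of node coordinates whose segment-sum pixel
#' length, multiplied by the emitted scale, reproduces the simulated mm
#' length, plus one 16 mm reference-strip polyline per plate. This
#' exercises the full tracing-to-mm path end to end.
#'
#' @param params a `sim_params`.
#' @param seed RNG seed (forwarded to [simulate_experiment()]).
#' @param condition `"WW"` or `"WS"`.
#' @param day 0, 1 or 2.
#' @param mm_per_pixel true image scale used to lay the nodes down
#'   (default 0.1 mm/pixel).
#' @param out_dir if non-`NULL`, writes `nodes.csv` (label, node, x, y) and
#'   `lengths.csv` there.
#' @return list with `nodes` (data.frame), `lengths` (data.frame of label,
#'   plate and mm), `strips` (named list of per-plate strip polylines) and
#'   `mm_per_pixel`.
#' @export
emit_tracings <- function(params = sim_params(), seed = 1L,
                          condition = c("WW", "WS"), day = 2L,
                          mm_per_pixel = 0.1, out_dir = NULL) {
  condition <- match.arg(condition)
  stopifnot(mm_per_pixel > 0, day %in% 0:2)
  sim <- simulate_experiment(params, seed)
  tbl <- sim[[tolower(condition)]][[paste0("day", day)]]
  tbl <- tbl[tbl$measurable & tbl$length_mm > 0, ]

  nodes <- list()
  add_polyline <- function(label, px_len, x0, y0, bend = TRUE) {
    if (bend && px_len > 0) {
      # an L-shaped tracing: short horizontal run then the vertical descent
      dx <- 0.1 * px_len
      nodes[[length(nodes) + 1L]] <<- data.frame(
        label = label, node = 1:3,
        x = c(x0, x0 + dx, x0 + dx),
        y = c(y0, y0, y0 + 0.9 * px_len)
      )
    } else {
      nodes[[length(nodes) + 1L]] <<- data.frame(
        label = label, node = 1:2, x = c(x0, x0 + px_len), y = c(y0, y0)
      )
    }
  }
  strips <- list()
  for (p in seq_len(params$n_plates)) {
    lab <- sprintf("plate%d_strip", p)
    px <- 16 / mm_per_pixel
    add_polyline(lab, px, x0 = 10, y0 = 10 + 30 * (p - 1), bend = FALSE)
    strips[[lab]] <- as_polyline(cbind(c(10, 10 + px), rep(10 + 30 * (p - 1), 2)))
  }
  for (i in seq_len(nrow(tbl))) {
    px_len <- tbl$length_mm[i] / mm_per_pixel
    add_polyline(paste0("plate", tbl$plate[i], "_", tbl$label[i]), px_len,
                 x0 = 50 + 40 * tbl$seedling[i], y0 = 100)
  }
  nodes <- do.call(rbind, nodes)
  lengths <- data.frame(
    label = paste0("plate", tbl$plate, "_", tbl$label),
    plate = tbl$plate, length_mm = tbl$length_mm, stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(nodes, file.path(out_dir, "nodes.csv"), row.names = FALSE)
    utils::write.csv(lengths, file.path(out_dir, "lengths.csv"),
                     row.names = FALSE)
  }
  list(nodes = nodes, lengths = lengths, strips = strips,
       mm_per_pixel = mm_per_pixel)
}
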