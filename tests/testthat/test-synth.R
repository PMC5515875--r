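test_that("simulation defaults reproduce the experiment's file layout", {
  dir <- withr::local_tempdir()
  sim <- simulate_experiment(sim_params(), seed = 1, out_dir = dir)
  folders <- list.dirs(dir, recursive = FALSE)
  expect_setequal(basename(folders),
                  c("WW day0", "WW day1", "WW day2",
                    "WS day0", "WS day1", "WS day2"))
  counts <- vapply(folders, function(f) length(list.files(f, "\\.csv$")), 0L)
  names(counts) <- basename(folders)
  # per-plate exports on days 0-1, per-seedling exports on day 2
  expect_equal(unname(counts[c("WW day0", "WW day1", "WS day0", "WS day1")]),
               rep(3L, 4))
  expect_equal(unname(counts[c("WW day2", "WS day2")]), rep(24L, 2))
  expect_true(file.exists(file.path(dir, "params.json")))

  # every filename and every label parses back through the grammar
  for (f in sim$files) {
    meta <- parse_filename(f)
    expect_s3_class(meta, "file_meta")
    tab <- read_export(f)
    expect_gt(nrow(tab), 0L)
  }
})

test_that("identical seeds give byte-identical experiments", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_experiment(sim_params(), seed = 42, out_dir = d1)
  s2 <- simulate_experiment(sim_params(), seed = 42, out_dir = d2)
  expect_identical(s1$truth, s2$truth)
  for (f in s1$files) {
    g <- file.path(d2, substring(f, nchar(d1) + 2))
    expect_identical(readBin(f, "raw", file.size(f)),
                     readBin(g, "raw", file.size(g)))
  }
  s3 <- simulate_experiment(sim_params(), seed = 43)
  expect_false(identical(s1$truth, s3$truth))
})

test_that("day-1 files are complete when nothing is occluded", {
  sim <- simulate_experiment(sim_params(occlusion_prob = 0), seed = 8)
  day1 <- sim$ww$day1
  # every seedling shows the shoot and roots 1-3; late roots not yet emerged
  expect_equal(nrow(day1), 24L * 4L)
  expect_setequal(unique(day1$structure), c("shoot", "root1", "root2", "root3"))
  expect_true(all(day1$measurable))
})

test_that("noise-free trajectories honour the stated growth features", {
  p <- sim_params()
  expect_equal(expected_length("root1", "WW", 0, p), 10)
  expect_equal(expected_length("root4", "WW", 1, p), 0)
  expect_equal(expected_length("root4", "WS", 1, p), 0)
  expect_gt(expected_length("root4", "WW", 2, p), 0)
  # growth decelerates for the early roots
  for (st in c("root1", "root2", "root3")) {
    r01 <- expected_length(st, "WW", 1, p) - expected_length(st, "WW", 0, p)
    r12 <- expected_length(st, "WW", 2, p) - expected_length(st, "WW", 1, p)
    expect_gte(r01, r12)
  }
  # stress multiplier 1 is the identity
  p1 <- sim_params(ws_root_mult = 1, ws_shoot_mult = 1)
  for (st in c("shoot", "root1", "root4"))
    for (d in 0:2)
      expect_equal(expected_length(st, "WS", d, p1),
                   expected_length(st, "WW", d, p1))
  # stress inhibits the shoot more than the roots
  shoot_ratio <- expected_length("shoot", "WS", 2, p) /
    expected_length("shoot", "WW", 2, p)
  root_ratio <- expected_length("root1", "WS", 2, p) /
    expected_length("root1", "WW", 2, p)
  expect_lt(shoot_ratio, root_ratio)
  expect_error(expected_length("stem", "WW", 1, p), "unknown structure")
})

test_that("invalid parameters are rejected with the fields named", {
  expect_error(sim_params(occlusion_prob = 2), "occlusion_prob")
  expect_error(sim_params(ws_root_mult = 0), "ws_root_mult")
  expect_error(sim_params(noise_sd = -1), "sds")
  expect_error(sim_params(emergence_day = c(root4 = 0.5, root5 = 1.5)),
               "later than 24 h")
  expect_error(sim_params(n_plates = 0), "n_plates")
})

test_that("emitted tracings reproduce tabulated lengths under the strip scale", {
  tr <- emit_tracings(sim_params(), seed = 6, condition = "WW", day = 2)
  cal <- calibrate(tr$strips[[1]], known_mm = 16)
  expect_equal(cal$mm_per_pixel, tr$mm_per_pixel, tolerance = 1e-12)
  expect_equal(measure_mm(tr$strips[[1]], cal), 16)

  polys <- split(tr$nodes, tr$nodes$label)
  for (i in seq_len(nrow(tr$lengths))) {
    lab <- tr$lengths$label[i]
    p <- as.matrix(polys[[lab]][order(polys[[lab]]$node), c("x", "y")])
    expect_equal(measure_mm(p, cal), tr$lengths$length_mm[i],
                 tolerance = 1e-6)
  }

  # nothing is traced for a root that has not emerged
  tr1 <- emit_tracings(sim_params(), seed = 6, condition = "WW", day = 1)
  expect_false(any(grepl("rt4|rt5|rt6", tr1$nodes$label)))

  # written node CSV reads back through the geometry module
  dir <- withr::local_tempdir()
  emit_tracings(sim_params(), seed = 6, day = 2, out_dir = dir)
  polys2 <- read_polylines(file.path(dir, "nodes.csv"))
  strip <- polys2[["plate1_strip"]]
  expect_equal(measure_mm(strip, calibrate(strip)), 16)
})

test_that("the pipeline round trip recovers the simulated means", {
  p <- sim_params()
  dir <- withr::local_tempdir()
  simulate_experiment(p, seed = 23, out_dir = dir)
  cc <- list(
    ww = compile_condition(
      merge_exports(file.path(dir, "WW day0")),
      merge_exports(file.path(dir, "WW day1")),
      merge_exports(file.path(dir, "WW day2"))
    ),
    ws = compile_condition(
      merge_exports(file.path(dir, "WS day0")),
      merge_exports(file.path(dir, "WS day1")),
      merge_exports(file.path(dir, "WS day2"))
    )
  )
  n <- 24
  for (cond in c("WW", "WS")) {
    compiled <- cc[[tolower(cond)]]
    for (st in c("shoot", "root1", "root2", "root3")) {
      for (d in 0:2) {
        # sd of a day-d mean: plate effects cluster, the rest averages out
        var_within <- p$seedling_sd^2 + (d + 1) * p$noise_sd^2
        sd_mean <- sqrt(p$plate_sd^2 / 3 + var_within / n)
        got <- structure_mean(compiled, st, d)$mean_mm
        want <- expected_length(st, cond, d, p)
        expect_lt(abs(got - want), 3 * sd_mean)
      }
    }
    # late roots: zero until emergence
    expect_equal(structure_mean(compiled, "root4", 0)$mean_mm, 0)
    expect_equal(structure_mean(compiled, "root5", 1)$mean_mm, 0)
  }
})
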