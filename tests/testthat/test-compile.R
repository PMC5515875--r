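# Six-seedling fixture exercising every status rule at once:
#   s5 root2 missing on day 1          -> occluded
#   s3 root4 traced "_NA" on day 1     -> occluded
#   s2 root4 measured (2 mm) on day 1  -> measured
#   everyone else's root4 on day 1     -> absent (0)
#   s6 absent from the day-1 photo     -> all structures occluded
#   root5 missing everywhere           -> absent on all days
make_fixture <- function() {
  early <- function(s, bump = 0) {
    rows_of(paste0("seed", s, c("sht", "rt1", "rt2", "rt3")),
            c(8, 10, 9, 7) + bump + s / 10)
  }
  day0 <- list(
    do.call(rbind, lapply(1:3, early)),
    do.call(rbind, lapply(4:6, early))
  )
  day1_p1 <- rbind(early(1, 5), early(2, 5), early(3, 5),
                   rows_of("seed2rt4", 2.0),
                   rows_of("seed3r4_NA", 1.1))
  day1_p2 <- rbind(early(4, 5),
                   early(5, 5)[-3, ])  # drop s5 root2
  day2 <- list(
    rbind(do.call(rbind, lapply(1:3, early, bump = 12)),
          rows_of(paste0("seed", 1:3, "rt4"), c(3, 3.5, 3.2))),
    rbind(do.call(rbind, lapply(4:6, early, bump = 12)),
          rows_of(paste0("seed", 4:6, "rt4"), c(3.1, 3.3, 2.9)))
  )
  list(
    day0 = make_day_table("WW", 0, day0),
    day1 = make_day_table("WW", 1, list(day1_p1, day1_p2)),
    day2 = make_day_table("WW", 2, day2)
  )
}

test_that("missing, _NA and absent records compile to the right statuses", {
  f <- make_fixture()
  cc <- compile_condition(f$day0, f$day1, f$day2)
  expect_s3_class(cc, "compiled_condition")
  expect_equal(attr(cc, "n_seedlings"), 6L)

  at <- function(s, st, d) cc[cc$seedling == s & cc$structure == st & cc$day == d, ]
  expect_equal(at(5, "root2", 1)$status, "occluded")
  expect_true(is.na(at(5, "root2", 1)$length_mm))
  expect_equal(at(3, "root4", 1)$status, "occluded")
  expect_equal(at(2, "root4", 1)$status, "measured")
  expect_equal(at(1, "root4", 1)$status, "absent")
  expect_equal(at(1, "root4", 1)$length_mm, 0)
  # missing photograph occludes the whole seedling, late roots included
  expect_setequal(at(6, "shoot", 1)$status, "occluded")
  expect_true(all(cc$status[cc$seedling == 6 & cc$day == 1] == "occluded"))
  # plate assignment follows day 0
  expect_equal(unique(cc$plate[cc$seedling <= 3]), 1L)
  expect_equal(unique(cc$plate[cc$seedling >= 4]), 2L)
})

test_that("means count absent zeros toward n and skip occluded replicates", {
  f <- make_fixture()
  cc <- compile_condition(f$day0, f$day1, f$day2)
  # day-1 root 4: measured 2.0 (s2), absent 0 (s1, s4, s5), occluded (s3, s6)
  m <- structure_mean(cc, "root4", 1)
  expect_equal(m$mean_mm, 2 / 4)
  expect_equal(m$n, 4L)
  # day-1 root 2: s5 occluded, s6 photo missing -> n = 4
  expect_equal(structure_mean(cc, "root2", 1)$n, 4L)
  # occluding root 2 must not touch root 1's n
  expect_equal(structure_mean(cc, "root1", 1)$n, 5L)

  # the {2.0, absent, occluded} cell in miniature
  mini <- list(
    day0 = make_day_table("WW", 0, list(
      rows_of(paste0("seed", rep(1:3, each = 4), c("sht", "rt1", "rt2", "rt3")),
              rep(c(8, 10, 9, 7), 3))
    )),
    day1 = make_day_table("WW", 1, list(rbind(
      rows_of(paste0("seed", rep(1:3, each = 4), c("sht", "rt1", "rt2", "rt3")),
              rep(c(12, 20, 18, 15), 3)),
      rows_of(c("seed1rt4", "seed3r4_NA"), c(2, 0.5))
    ))),
    day2 = make_day_table("WW", 2, list(rbind(
      rows_of(paste0("seed", rep(1:3, each = 4), c("sht", "rt1", "rt2", "rt3")),
              rep(c(15, 30, 28, 25), 3)),
      rows_of(paste0("seed", 1:3, "rt4"), c(5, 4, 4.5))
    )))
  )
  cc2 <- compile_condition(mini$day0, mini$day1, mini$day2)
  m2 <- structure_mean(cc2, "root4", 1)
  expect_equal(m2$mean_mm, 1.0)
  expect_equal(m2$n, 2L)
  # a fully occluded cell has no mean, not a zero mean
  expect_true(is.na(structure_mean(cc2, "root5", 1)$mean_mm) ||
                structure_mean(cc2, "root5", 1)$n > 0)
})

test_that("status counts partition the seedlings for every structure and day", {
  f <- make_fixture()
  cc <- compile_condition(f$day0, f$day1, f$day2)
  counts <- table(cc$structure, cc$day)
  expect_true(all(counts == attr(cc, "n_seedlings")))
  agg <- aggregate(seedling ~ structure + day, data = cc, FUN = length)
  expect_true(all(agg$seedling == 6L))

  sim <- simulate_experiment(sim_params(occlusion_prob = 0.2), seed = 3)
  cc24 <- compile_sim(sim)$ww
  for (st in attr(cc24, "structures")) {
    for (d in 0:2) {
      sub <- cc24[cc24$structure == st & cc24$day == d, ]
      expect_equal(nrow(sub), 24L)
      expect_equal(sum(sub$status %in% c("measured", "absent", "occluded")), 24L)
    }
  }
})

test_that("occluding one structure of one seedling changes no other cell's n", {
  f <- make_fixture()
  base <- compile_condition(f$day0, f$day1, f$day2)
  # mutate: delete s1's root3 tracing from day 1
  day1_mut <- f$day1[!(f$day1$seedling == 1 & f$day1$structure == "root3"), ]
  mut <- compile_condition(f$day0, day1_mut, f$day2)
  for (st in attr(base, "structures")) {
    for (d in 0:2) {
      n0 <- structure_mean(base, st, d)$n
      n1 <- structure_mean(mut, st, d)$n
      if (st == "root3" && d == 1) {
        expect_equal(n1, n0 - 1L)
      } else {
        expect_equal(n1, n0)
      }
    }
  }
})

test_that("compile-stage means agree exactly with brute-force enumeration", {
  sim <- simulate_experiment(
    sim_params(occlusion_prob = 0.25, root6_prob = 0.3), seed = 17
  )
  for (cond in c("ww", "ws")) {
    days <- sim[[cond]]
    cc <- compile_condition(days$day0, days$day1, days$day2)
    seedlings <- sort(unique(as.data.frame(days$day0)$seedling))
    for (st in attr(cc, "structures")) {
      for (d in 0:2) {
        got <- structure_mean(cc, st, d)
        want <- oracle_mean(list(days$day0, days$day1, days$day2),
                            seedlings, st, d)
        expect_identical(got$n, want$n)
        expect_equal(got$mean_mm, want$mean, tolerance = 0)
      }
    }
  }
})

test_that("contradictory and malformed day sets are rejected", {
  f <- make_fixture()
  # emerged root 4 cannot be scored absent later
  day2_bad <- f$day2[!(f$day2$seedling == 2 & f$day2$structure == "root4"), ]
  expect_error(compile_condition(f$day0, f$day1, day2_bad), "inconsistent")
  # unknown seedling on day 1
  extra <- make_day_table("WW", 1, list(rows_of("seed9rt1", 10)))
  day1_bad <- rbind(as.data.frame(f$day1), as.data.frame(extra))
  class(day1_bad) <- class(f$day1)
  expect_error(compile_condition(f$day0, day1_bad, f$day2), "unknown seedling")
  # mixed conditions
  ws0 <- make_day_table("WS", 0, list(rows_of("seed1rt1", 10)))
  expect_error(compile_condition(ws0, f$day1, f$day2), "mix conditions|unknown")
  # wrong day slot
  expect_error(compile_condition(f$day1, f$day1, f$day2), "day0 input")
})

test_that("suspicious but legal data warns without being dropped", {
  f <- make_fixture()
  # measured length shrinking between days
  day2_shrunk <- f$day2
  i <- which(day2_shrunk$seedling == 1 & day2_shrunk$structure == "root1")
  day2_shrunk$length_mm[i] <- 1
  expect_warning(compile_condition(f$day0, f$day1, day2_shrunk),
                 "decreases")
  cc <- suppressWarnings(compile_condition(f$day0, f$day1, day2_shrunk))
  expect_equal(cc$length_mm[cc$seedling == 1 & cc$structure == "root1" &
                              cc$day == 2], 1)
  # an early structure missing from a day-2 photograph
  day2_gap <- f$day2[!(f$day2$seedling == 4 & f$day2$structure == "shoot"), ]
  expect_warning(compile_condition(f$day0, f$day1, day2_gap),
                 "expected visible")
})

test_that("the sixth root is included only above the evidence threshold", {
  build <- function(k) {
    early <- rows_of(paste0("seed", rep(1:8, each = 4),
                            c("sht", "rt1", "rt2", "rt3")),
                     rep(c(8, 10, 9, 7), 8))
    grown <- early
    grown$Length <- grown$Length + 10
    day2 <- rbind(grown, if (k > 0) rows_of(paste0("seed", 1:k, "rt6"),
                                            rep(2, k)))
    compile_condition(
      make_day_table("WW", 0, list(early)),
      make_day_table("WW", 1, list(early)),
      make_day_table("WW", 2, list(day2))
    )
  }
  expect_false(root6_included(build(3)))
  expect_true(root6_included(build(4)))
  expect_true(root6_included(build(1), threshold = 0))
  expect_false(root6_included(build(0), threshold = 0))
})

test_that("growth increments average matched seedlings only", {
  f <- make_fixture()
  cc <- suppressWarnings(compile_condition(f$day0, f$day1, f$day2))
  gi <- growth_increments(cc)
  expect_s3_class(gi, "growth_segments")
  # root1: day0 -> day1 is +5 for the five photographed seedlings
  r1 <- gi[gi$structure == "root1" & gi$interval == "day0_1", ]
  expect_equal(r1$mean_change_mm, 5)
  expect_equal(r1$n, 5L)
  # s6 is excluded from both root-1 intervals (day-1 photo missing)
  r1b <- gi[gi$structure == "root1" & gi$interval == "day1_2", ]
  expect_equal(r1b$n, 5L)

  # single seedling 10 -> 25 -> 41
  single <- compile_condition(
    make_day_table("WW", 0, list(rows_of(c("seed1sht", "seed1rt1", "seed1rt2",
                                           "seed1rt3"), c(5, 10, 9, 8)))),
    make_day_table("WW", 1, list(rows_of(c("seed1sht", "seed1rt1", "seed1rt2",
                                           "seed1rt3"), c(7, 25, 20, 18)))),
    make_day_table("WW", 2, list(rows_of(c("seed1sht", "seed1rt1", "seed1rt2",
                                           "seed1rt3"), c(9, 41, 30, 28))))
  )
  gi1 <- growth_increments(single)
  expect_equal(gi1[gi1$structure == "root1", "mean_change_mm"], c(15, 16))

  # negative increments are preserved with a warning
  shrink <- compile_condition(
    make_day_table("WW", 0, list(rows_of(c("seed1sht", "seed1rt1", "seed1rt2",
                                           "seed1rt3"), c(5, 10, 9, 8)))),
    make_day_table("WW", 1, list(rows_of(c("seed1sht", "seed1rt1", "seed1rt2",
                                           "seed1rt3"), c(7, 25, 20, 18)))),
    make_day_table("WW", 2, list(rows_of(c("seed1sht", "seed1rt1", "seed1rt2",
                                           "seed1rt3"), c(9, 24, 30, 28))))
  ) |> suppressWarnings()
  expect_warning(growth_increments(shrink), "negative")
  gi2 <- suppressWarnings(growth_increments(shrink))
  expect_equal(gi2[gi2$structure == "root1" & gi2$interval == "day1_2",
                   "mean_change_mm"], -1)
})
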