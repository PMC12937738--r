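test_that("urgency coefficient is the exact fraction 360/li", {
  expect_equal(as.numeric(urgency_coefficient(360)), 1)
  expect_equal(as.numeric(urgency_coefficient(30)), 12)
  u7 <- urgency_coefficient(7)
  expect_identical(c(u7$num, u7$den), c(360L, 7L))
  expect_identical(u7$num, 360L %/% 1L)  # 360/7 already reduced
  # exactness: num/den * li == 360 in integer arithmetic for many deadlines
  for (li in c(7L, 11L, 13L, 30L, 48L, 97L, 360L)) {
    u <- urgency_coefficient(li)
    expect_identical(u$num * (li %/% u$den), 360L)
    expect_identical(li %% u$den, 0L)
  }
  expect_error(urgency_coefficient(0), "positive")
  expect_error(urgency_coefficient(-5), "positive")
})

test_that("assignment and exclusion penalties match hand evaluation", {
  expect_equal(assignment_penalty(mi = 0, li = 360, d = 1), 1)
  expect_equal(assignment_penalty(mi = 28, li = 30, d = 5), 96)
  expect_equal(assignment_penalty(mi = 100, li = 180, d = 2), 4)
  expect_error(assignment_penalty(mi = 0, li = 30, d = 0), "positive")
  expect_equal(exclusion_penalty(mi = 0, li = 360, horizon_days = 2), 3)
  expect_equal(exclusion_penalty(mi = 28, li = 30, horizon_days = 2), 384)
  # alternative weighting: urgency multiplies only the tardiness term
  expect_equal(assignment_penalty(28, 30, 5, weighting = "tardiness_only"),
               5 + 3 * 12)
})

test_that("penalty table invariants hold on generated instances", {
  for (seed in 1:5) {
    inst <- generate_instance(generator_config(n_patients = 15, seed = seed))
    pt <- penalty_table(inst)
    # exclusion always costlier than any in-horizon assignment
    expect_true(all(pt$q > pt$p + 1e-12))
    # monotone non-decreasing in day; strictly increasing once tardy
    diffs <- t(apply(pt$p, 1, diff))
    expect_true(all(diffs > 0))
    # rational-vs-float agreement: penalties recomputed via exact fractions
    for (i in seq_len(nrow(inst$patients))) {
      li <- inst$patients$deadline_days[i]
      mi <- inst$patients$waited_days[i]
      u <- urgency_coefficient(li)
      for (d in seq_len(inst$horizon_days)) {
        exact <- (d + max(mi + d - li, 0)) * u$num / u$den
        expect_equal(pt$p[i, d], exact, tolerance = 1e-9)
      }
    }
  }
})

test_that("max_positions floors capacity over minimum duration", {
  mk <- function(durs, cap) {
    pats <- data.frame(id = paste0("P", seq_along(durs)),
                       duration_slots = durs,
                       deadline_days = 360L, waited_days = 0L)
    new_instance(pats, 14L, 1L, capacity = cap, emergency_classes = 2L)
  }
  expect_equal(max_positions(mk(c(2L, 8L), 24L)), 12L)
  expect_equal(max_positions(mk(c(5L, 7L), 24L)), 4L)
  expect_equal(max_positions(mk(12L, 12L)), 1L)
})

test_that("weekend mask blocks exactly the multiples of 6 or 7", {
  a <- default_compatibility(3, 14, 2)
  blocked <- which(apply(a[1, , ] == 0, 1, all))
  expect_identical(blocked, c(6L, 7L, 12L, 14L))
  expect_identical(blocked_days(5), integer(0))
  expect_identical(blocked_days(28), c(6L, 7L, 12L, 14L, 18L, 21L, 24L, 28L))
  # identical across patients and ORs
  for (i in 1:3) for (j in 1:2)
    expect_identical(which(a[i, , j] == 0), blocked)
  expect_error(default_compatibility(0, 14, 2), "positive")
})

test_that("instance JSON round-trips losslessly", {
  inst <- generate_instance(generator_config(n_patients = 8, seed = 3))
  f <- tempfile(fileext = ".json")
  write_instance(inst, f)
  back <- read_instance(f)
  expect_identical(back$patients$id, inst$patients$id)
  expect_identical(back$patients$duration_slots, inst$patients$duration_slots)
  expect_identical(back$patients$deadline_days, inst$patients$deadline_days)
  expect_identical(back$patients$waited_days, inst$patients$waited_days)
  expect_equal(back$capacity, inst$capacity)
  expect_identical(back$compatibility, inst$compatibility)
  expect_identical(back$emergency_classes, inst$emergency_classes)
  unlink(f)
})

test_that("CSV waiting list reader enforces the column contract", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(id = c("A", "B"), duration_slots = c(4L, 6L),
                   deadline_days = c(60L, 90L), waited_days = c(10L, 0L))
  write.csv(df, f, row.names = FALSE)
  got <- read_waiting_list(f)
  expect_equal(got$duration_slots, c(4L, 6L))
  writeLines("id,foo\nA,1", f)
  expect_error(read_waiting_list(f), "columns")
  unlink(f)
})

test_that("instance validation rejects broken parameterizations", {
  pats <- data.frame(id = "P1", duration_slots = 4L, deadline_days = 30L,
                     waited_days = 0L)
  expect_error(new_instance(pats, 14L, 2L, delta_noshow = 9L, delta_max = 7L),
               "delay")
  expect_error(new_instance(pats, 2L, 1L, delta_noshow = 2L), "horizon")
  expect_error(new_instance(pats, 14L, 2L, emergency_classes = c(40L)),
               "fit")
  expect_error(new_instance(pats[0, ], 14L, 2L), "no patients")
})

test_that("emergency moments are the 0-based slots of the protected days", {
  inst <- tiny_instance()
  expect_identical(emergency_moments(inst), 0:11)
})
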