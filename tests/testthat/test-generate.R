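test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_patients = 40, horizon_days = 14, num_ors = 2,
                          mix = "A", seed = 1)
  f1 <- tempfile(); f2 <- tempfile()
  write_instance(generate_instance(cfg), f1)
  write_instance(generate_instance(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  cfg2 <- generator_config(n_patients = 40, seed = 2)
  expect_false(identical(generate_instance(cfg)$patients,
                         generate_instance(cfg2)$patients))
  unlink(c(f1, f2))
  # the generator must not disturb the caller's RNG stream
  set.seed(99); a <- runif(1)
  set.seed(99); invisible(generate_instance(cfg)); b <- runif(1)
  expect_identical(a, b)
})

test_that("generated instances satisfy the benchmark parameterization", {
  inst <- generate_instance(generator_config(n_patients = 40, horizon_days = 14,
                                             num_ors = 2, seed = 1))
  expect_equal(unique(as.vector(inst$capacity)), 24L)
  expect_equal(inst$overtime_slots, 4L)
  expect_equal(inst$delta_max, 7L)
  expect_equal(inst$delta_noshow, 2L)
  expect_equal(inst$emergency_classes, c(4L, 8L, 16L))
  expect_equal(inst$slot_minutes, 15L)
  # weekends blocked for every patient
  for (d in c(6L, 7L, 12L, 14L))
    expect_true(all(inst$compatibility[, d, ] == 0))
  for (d in setdiff(1:14, c(6, 7, 12, 14)))
    expect_true(all(inst$compatibility[, d, ] == 1))
})

test_that("sampled patients respect their bounds at scale", {
  inst <- generate_instance(generator_config(n_patients = 120,
                                             horizon_days = 28, num_ors = 3,
                                             mix = "C", seed = 7))
  p <- inst$patients
  expect_equal(nrow(p), 120L)
  expect_true(all(p$duration_slots >= 1 & p$duration_slots <= 24))
  expect_true(all(p$waited_days >= 0 & p$waited_days < p$deadline_days))
  expect_true(all(p$deadline_days %in% urgency_deadlines()))
  validate_instance(inst)
  # nobody incompatible with every (day, OR)
  expect_true(all(apply(inst$compatibility, 1, sum) > 0))
})

test_that("empirical frequencies match the configured distributions", {
  cfg <- generator_config(n_patients = 10000, horizon_days = 14,
                          num_ors = 2, mix = "B", seed = 11)
  inst <- generate_instance(cfg)
  # chi-square goodness of fit, durations
  obs <- table(factor(inst$patients$duration_slots,
                      levels = names(cfg$duration_probs)))
  gof <- suppressWarnings(chisq.test(obs, p = cfg$duration_probs))
  expect_gt(gof$p.value, 0.01)
  # and urgency classes (via deadlines)
  dl <- urgency_deadlines()
  obs_u <- table(factor(inst$patients$deadline_days, levels = dl))
  gof_u <- suppressWarnings(chisq.test(obs_u, p = cfg$urgency_probs))
  expect_gt(gof_u$p.value, 0.01)
})

test_that("the case-study list is 54 patients skewed toward urgent classes", {
  share_most_urgent <- function(inst)
    mean(inst$patients$deadline_days == urgency_deadlines()[["i"]])
  cs <- vapply(1:100, function(s)
    share_most_urgent(case_study_instance(seed = s)), numeric(1))
  bm <- vapply(1:100, function(s) {
    inst <- generate_instance(generator_config(n_patients = 54, seed = s,
                                               mix = "A"))
    share_most_urgent(inst)
  }, numeric(1))
  expect_equal(nrow(case_study_instance(1)$patients), 54L)
  expect_gt(mean(cs), mean(bm))
  # both horizon/OR variants of the case study are supported
  v <- case_study_instance(2, horizon_days = 28, num_ors = 3)
  expect_equal(v$horizon_days, 28L)
  expect_equal(v$num_ors, 3L)
  # reproducible
  expect_identical(case_study_instance(5)$patients,
                   case_study_instance(5)$patients)
})

test_that("config validation rejects impossible duration supports", {
  expect_error(generator_config(duration_probs = c(`30` = 1)), "capacity")
  expect_error(generator_config(duration_probs = c(`0` = 1)), "slot")
})
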