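test_that("the oracle reproduces the TINY enumeration exactly", {
  orc <- brute_force_nominal(tiny_instance())
  expect_equal(orc$objective, 19)
  expect_length(orc$argmins, 1)                  # unique argmin
  am <- orc$argmins[[1]]
  expect_equal(am$day[am$patient == "P1"], 1)
  expect_equal(am$day[am$patient == "P3"], 2)
  expect_equal(am$day[am$patient == "P2"], 0)    # unscheduled
  expect_lte(orc$states, 27)                     # at most 3 choices each
})

test_that("oracle degenerate cases are exact", {
  one <- data.frame(id = "A", duration_slots = 4L, deadline_days = 60L,
                    waited_days = 10L)
  inst <- new_instance(one, 3L, 1L, capacity = 8L, delta_noshow = 1L,
                       emergency_classes = 2L,
                       compatibility = array(1L, c(1, 3, 1)))
  orc <- brute_force_nominal(inst)
  expect_equal(orc$objective, penalty_table(inst)$p[1, 1])
  # all incompatible: everyone excluded
  inst0 <- new_instance(one, 3L, 1L, capacity = 8L, delta_noshow = 1L,
                        emergency_classes = 2L,
                        compatibility = array(0L, c(1, 3, 1)))
  expect_equal(brute_force_nominal(inst0)$objective,
               penalty_table(inst0)$q[[1]])
  # guard rails refuse big instances
  expect_error(brute_force_nominal(small_bench_instance(1)), "guard rails")
})

test_that("oracle and MILP agree on random tiny instances", {
  # a quick smoke sample here; the full 50-seed sweep runs in the
  # acceptance suite
  for (seed in 1:8) {
    inst <- random_tiny_instance(seed)
    orc <- brute_force_nominal(inst)
    sol <- solve_model(build_nominal_model(inst), time_limit = 30)
    expect_equal(sol$objective, orc$objective, label = paste("seed", seed))
  }
})

test_that("exhaustive restoration check accepts pipeline bundles on TINY", {
  b <- tiny_bundle("heuristic")
  chk <- exhaustive_rs_check(b)
  expect_true(all(is.finite(chk$emergency$oracle)))
  expect_true(chk$ok)
  # per-scenario penalties can never beat the enumerated optimum
  expect_true(all(chk$emergency$bundle >= chk$emergency$oracle - 1e-6))
  expect_true(all(chk$noshow$bundle >= chk$noshow$oracle - 1e-6))
})
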