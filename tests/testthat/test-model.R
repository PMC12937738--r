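test_that("nominal model has the expected shape", {
  pats <- data.frame(id = c("A", "B", "C"), duration_slots = c(2L, 3L, 4L),
                     deadline_days = 360L, waited_days = 0L)
  inst <- new_instance(pats, 2L, 1L, capacity = 12L, delta_noshow = 1L,
                       emergency_classes = 4L,
                       compatibility = array(1L, c(3, 2, 1)))
  m <- build_nominal_model(inst)
  expect_equal(m$nvar, 6L)                      # 3 patients x 2 days x 1 OR
  fams <- model_families(m)
  expect_equal(fams$eq4, 3L)                    # one at-most-once row each
  expect_equal(fams$eq6, 2L)                    # one capacity row per OR-day
  expect_identical(fams$eq5, "bounds")          # compatibility via bounds
  expect_equal(m$objective_id, "nominal")
})

test_that("TINY nominal optimum is 19 with the enumerated assignment", {
  sol <- solve_nominal(tiny_instance(), solve_config(time_limit = 30))
  expect_equal(sol$objective, 19)
  x <- sol$x_star
  expect_equal(x[1, 1, 1], 1)                   # P1 on day 1
  expect_equal(x[3, 2, 1], 1)                   # P3 on day 2
  expect_equal(sum(x[2, , ]), 0)                # P2 excluded
})

test_that("fully incompatible instances pay the full exclusion penalty", {
  pats <- data.frame(id = c("A", "B"), duration_slots = c(2L, 3L),
                     deadline_days = c(60L, 90L), waited_days = c(5L, 50L))
  inst <- new_instance(pats, 2L, 1L, capacity = 12L, delta_noshow = 1L,
                       emergency_classes = 4L,
                       compatibility = array(0L, c(2, 2, 1)))
  m <- build_nominal_model(inst)
  sol <- solve_model(m, time_limit = 30)
  expect_equal(sol$objective, sum(penalty_table(inst)$q))
})

test_that("complete model registers all 46 printed constraint families", {
  m <- build_complete_model(tiny_instance())
  fams <- model_families(m)
  expected <- paste0("eq", setdiff(4:49, c(7, 42)))   # (7) is a formula,
  # (41) xor (42): fixed-delay mode active here
  for (e in expected) expect_true(!is.null(fams[[e]]), label = e)
  expect_identical(fams$eq26, "alias:eq11")           # (26) restates (11)
  m2 <- build_complete_model(tiny_instance(), noshow_mode = "window")
  expect_true(is.null(model_families(m2)$eq41))
  expect_false(is.null(model_families(m2)$eq42))
})

test_that("scenario enumeration matches the index-set products", {
  sc <- enumerate_scenarios(tiny_instance())
  expect_equal(nrow(sc$emergency), 12 * 1 * 2)        # |H| x |W| x |L|
  expect_lte(nrow(sc$noshow), 3)
  inst40 <- small_bench_instance(seed = 5)
  sc40 <- enumerate_scenarios(inst40)
  expect_equal(nrow(sc40$emergency), 24 * 1 * 3)      # 72 triples
  expect_equal(nrow(sc40$noshow), 20)                 # all compatible on day 1
  # variable-count example: TINY xbar has 24 scenarios x |I| x |D| x |J|
  m <- build_complete_model(tiny_instance())
  expect_equal(prod(m$vars[["xbar"]]$dim), 24 * 3 * 2 * 1)
})

test_that("the emergency capacity cut is instantiated as min(gamma, T-h)", {
  pats <- data.frame(id = sprintf("P%d", 1:4),
                     duration_slots = c(4L, 6L, 8L, 5L),
                     deadline_days = 360L, waited_days = 0L)
  inst <- new_instance(pats, 3L, 1L, capacity = 24L,
                       emergency_classes = 16L, delta_noshow = 2L,
                       compatibility = array(1L, c(4, 3, 1)))
  m <- build_complete_model(inst)
  # family eq36 rows are laid out over (j, h, g, l); h = 7 is local row 8
  row <- constraint_row(m, "eq36", k = 8L)
  expect_equal(row$hi, 24 + 4)                        # T + overtime
  eta_id <- vid(m, "eta", 8L, 1L, 1L)                 # stored at h+1
  expect_equal(row$coefs[row$vars == eta_id], min(16, 24 - 7))
  # and near end-of-day the cut shrinks to the remaining time
  row23 <- constraint_row(m, "eq36", k = 24L)         # h = 23
  eta23 <- vid(m, "eta", 24L, 1L, 1L)
  expect_equal(row23$coefs[row23$vars == eta23], 24 - 23)
})

test_that("auxiliary blocks enforce their reference solutions", {
  inst <- tiny_instance()
  s1 <- solve_nominal(inst, solve_config(time_limit = 30))
  # block ii keeps the protected-day admissions
  m <- build_complete_model(inst)
  attach_auxiliary_block(m, "ii", s1$x_star)
  sol <- solve_model(m, time_limit = 60)
  x <- solution_values(m, sol, "x")
  expect_gte(sum(x[, 1, ] * s1$x_star[, 1, ]), sum(s1$x_star[, 1, ]))
  # block i: zero difference attainable when the reference is feasible
  m2 <- build_complete_model(inst)
  attach_auxiliary_block(m2, "i", s1$x_star)
  set_objective(m2, "difference")
  sol2 <- solve_model(m2, time_limit = 60)
  expect_equal(sol2$objective, 0)
  # re-attaching is refused; missing references are refused
  expect_error(attach_auxiliary_block(m2, "i", s1$x_star), "already")
  expect_error(attach_auxiliary_block(m2, "iii", NULL), "reference")
  expect_error(set_objective(build_complete_model(inst), "difference"),
               "block i")
})

test_that("objective switching never drops constraints", {
  m <- build_complete_model(tiny_instance())
  n0 <- m$ncon
  for (k in c("emergency", "noshow", "nominal")) {
    set_objective(m, k)
    expect_equal(m$ncon, n0)
  }
  expect_equal(m$objective_id, "nominal")
})

test_that("LP relaxation bounds the integer optimum", {
  inst <- random_tiny_instance(3)
  m <- build_nominal_model(inst)
  rel <- solve_model(m, time_limit = 30, relax = TRUE)
  mip <- solve_model(m, time_limit = 30)
  expect_lte(rel$objective, mip$objective + 1e-6)
})

test_that("robustness is free when the nominal schedule leaves slack and a substitute", {
  # unique nominal optimum: A and B on day 1 (8 slots, full), C on day 2;
  # emergencies never exceed the overtime allowance and C can substitute
  # either day-1 patient, so the complete optimum coincides with the
  # nominal one.  (With every patient on day 1 the equality is structurally
  # impossible: a substitute must be nominally scheduled the day after.)
  pats <- data.frame(id = c("A", "B", "C"), duration_slots = c(4L, 4L, 4L),
                     deadline_days = c(30L, 60L, 360L), waited_days = 0L)
  inst <- new_instance(pats, 3L, 1L, capacity = 8L,
                       emergency_classes = c(2L, 4L), delta_noshow = 1L,
                       compatibility = array(1L, c(3, 3, 1)))
  nom <- solve_model(build_nominal_model(inst), time_limit = 30)
  com <- solve_model(build_complete_model(inst), time_limit = 60)
  expect_equal(nom$objective, 20)               # 1*12 + 1*6 + 2*1
  expect_equal(com$objective, nom$objective)
})
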