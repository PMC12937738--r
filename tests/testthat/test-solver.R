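test_that("the backend reports optimality, bounds and incumbents coherently", {
  m <- build_nominal_model(tiny_instance())
  sol <- solve_model(m, time_limit = 30)
  expect_equal(sol$status, "optimal")
  expect_lte(sol$bound, sol$objective + 1e-9)
  expect_length(sol$x, m$nvar)
  # binaries come back integral
  expect_true(all(abs(sol$x - round(sol$x)) < 1e-6))
  # deterministic: identical incumbent on a re-solve
  sol2 <- solve_model(m, time_limit = 30)
  expect_identical(sol$x, sol2$x)
})

test_that("infeasible models are reported as such", {
  pats <- data.frame(id = "A", duration_slots = 4L, deadline_days = 30L,
                     waited_days = 0L)
  inst <- new_instance(pats, 3L, 1L, capacity = 8L, delta_noshow = 1L,
                       emergency_classes = 2L,
                       compatibility = array(1L, c(1, 3, 1)))
  m <- build_nominal_model(inst)
  # force the patient scheduled nowhere and everywhere at once
  .gone <- m$lb[vid(m, "x", 1L, 1L, 1L)] <- 1
  m$lb[vid(m, "x", 1L, 2L, 1L)] <- 1
  sol <- solve_model(m, time_limit = 10)
  expect_equal(sol$status, "infeasible")
  expect_null(sol$x)
})

test_that("LP-format export renders a readable model", {
  m <- build_nominal_model(tiny_instance())
  f <- tempfile(fileext = ".lp")
  write_lp(m, f)
  txt <- readLines(f)
  expect_true(any(grepl("^Minimize", txt)))
  expect_true(any(grepl("^Subject To", txt)))
  expect_true(any(grepl("^General", txt)))
  expect_equal(sum(grepl("^ c", txt)), m$ncon)
  unlink(f)
})

test_that("solution_values reshapes families with their index dimensions", {
  m <- build_complete_model(tiny_instance())
  sol <- solve_model(m, time_limit = 60)
  x <- solution_values(m, sol, "x")
  expect_equal(dim(x), c(3, 2, 1))
  xb <- solution_values(m, sol, "xbar")
  expect_equal(dim(xb), c(12, 1, 2, 3, 2, 1))
  expect_error(solution_values(m, sol, "nope"), "unknown")
})
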