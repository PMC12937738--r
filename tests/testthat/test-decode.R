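# Hand-built bundles for decoder/validator checks, assembled without any
# solver involvement.

blank_bundle <- function(inst) {
  nI <- nrow(inst$patients); nD <- inst$horizon_days; nJ <- inst$num_ors
  nW <- inst$rs_days; nH <- length(emergency_moments(inst))
  nL <- length(inst$emergency_classes); nS <- max_positions(inst)
  structure(list(
    instance = inst,
    x = array(0, c(nI, nD, nJ)), y = array(0, c(nI, nW, nJ, nS)),
    xi = array(0, c(nI, nW, nJ)), C = array(0, c(nW, nJ)),
    eta = array(0, c(nH, nW, nJ)), chi = array(0, c(nH, nW, nI)),
    xbar = array(0, c(nH, nW, nL, nI, nD, nJ)),
    mu = array(0, c(nH, nW, nL, nI)),
    theta = array(0, c(nI, nW, nJ)),
    xhat = array(0, c(nI, nW, nI, nD, nJ)),
    noshow_mode = "fixed_delay", metrics = list(), config = NULL),
    class = "schedule_bundle")
}

two_patient_instance <- function() {
  pats <- data.frame(id = c("A", "B"), duration_slots = c(8L, 6L),
                     deadline_days = c(60L, 90L), waited_days = c(0L, 0L))
  new_instance(pats, 3L, 1L, capacity = 24L, emergency_classes = 4L,
               delta_noshow = 1L, compatibility = array(1L, c(2, 3, 1)))
}

test_that("start slots are the cumulative durations of predecessors", {
  inst <- two_patient_instance()
  b <- blank_bundle(inst)
  b$x[1, 1, 1] <- 1; b$x[2, 1, 1] <- 1
  b$y[1, 1, 1, 1] <- 1; b$y[2, 1, 1, 2] <- 1    # order A(t=8) then B(t=6)
  b$xi[1, 1, 1] <- 1; b$xi[2, 1, 1] <- 9
  b$C[1, 1] <- 15
  dec <- decode_schedule(b)[[1]][[1]]
  expect_equal(dec$start, c(1, 9))
  expect_equal(dec$completion, 15)
  expect_equal(dec$idle_tail, 24 + 1 - 15)
  # a wrong stored start is an error naming the ordering rule
  b$xi[2, 1, 1] <- 10
  expect_error(decode_schedule(b), "ordering-implied")
  # duplicated positions are a structural error
  b$xi[2, 1, 1] <- 9
  b$y[2, 1, 1, 2] <- 0; b$y[2, 1, 1, 1] <- 1
  expect_error(decode_schedule(b), "gap-free|position")
})

test_that("empty ORs decode with zero completion and full idle tail", {
  b <- blank_bundle(two_patient_instance())
  dec <- decode_schedule(b)[[1]][[1]]
  expect_equal(dec$completion, 0)
  expect_length(dec$patients, 0)
})

test_that("capacity overruns surface as block-A violations with slack", {
  pats <- data.frame(id = c("A", "B", "C"),
                     duration_slots = c(10L, 10L, 5L),
                     deadline_days = 360L, waited_days = 0L)
  inst <- new_instance(pats, 3L, 1L, capacity = 24L, emergency_classes = 4L,
                       delta_noshow = 1L,
                       compatibility = array(1L, c(3, 3, 1)))
  b <- blank_bundle(inst)
  b$x[1, 1, 1] <- 1; b$x[2, 1, 1] <- 1; b$x[3, 1, 1] <- 1   # 25 > 24
  b$y[1, 1, 1, 1] <- 1; b$y[2, 1, 1, 2] <- 1; b$y[3, 1, 1, 3] <- 1
  b$xi[1, 1, 1] <- 1; b$xi[2, 1, 1] <- 11; b$xi[3, 1, 1] <- 21
  b$C[1, 1] <- 26
  rep <- validate_bundle(b)
  eq6 <- rep[rep$eq == "eq6", ]
  expect_equal(nrow(eq6), 1)
  expect_equal(eq6$slack, -1)
})

test_that("anticipating a patient in a no-show plan violates the ban", {
  inst <- two_patient_instance()
  b <- blank_bundle(inst)
  b$x[1, 1, 1] <- 1                      # A on day 1
  b$x[2, 2, 1] <- 1                      # B on day 2
  b$y[1, 1, 1, 1] <- 1; b$xi[1, 1, 1] <- 1; b$C[1, 1] <- 9
  b$theta[2, 1, 1] <- 1                  # B designated substitute
  # no-show of A: B covers on day 1, A returns on day 2 -- legal
  b$xhat[1, 1, 2, 1, 1] <- 1
  b$xhat[1, 1, 1, 2, 1] <- 1
  # scenario keyed by B (not scheduled day 1, vacuous): keep nominal
  b$xhat[2, 1, 1, 1, 1] <- 1
  b$xhat[2, 1, 2, 2, 1] <- 1
  rep0 <- validate_bundle(b)
  expect_equal(nrow(rep0[rep0$block %in% c("G", "H"), ]), 0)
  # tamper: in A's scenario, B is also pulled to day 1 in the OTHER sense --
  # anticipate A itself from day 2 in B's scenario
  b2 <- b
  b2$xhat[2, 1, 1, 1, 1] <- 1            # A stays day 1 (nominal) -- fine
  b2$x[1, 1, 1] <- 0; b2$x[1, 2, 1] <- 1 # move A nominally to day 2
  b2$y[1, 1, 1, 1] <- 0; b2$xi[1, 1, 1] <- 0; b2$C[1, 1] <- 0
  rep2 <- validate_bundle(b2)
  expect_gt(nrow(rep2[rep2$eq %in% c("eq47", "eq47b"), ]), 0)
})

test_that("objective re-evaluation matches direct penalty arithmetic", {
  inst <- two_patient_instance()
  pt <- penalty_table(inst)
  b <- blank_bundle(inst)
  expect_equal(evaluate_objective(b, "nominal"), sum(pt$q))   # nobody in
  b$x[1, 1, 1] <- 1
  expect_equal(evaluate_objective(b, "nominal"), pt$p[1, 1] + pt$q[[2]])
  # restoration plans identical to the nominal assignment average to the
  # same penalty value
  for (h in seq_len(dim(b$xbar)[1])) for (l in seq_len(dim(b$xbar)[3]))
    b$xbar[h, 1, l, 1, 1, 1] <- 1
  expect_equal(evaluate_objective(b, "emergency"),
               evaluate_objective(b, "nominal"))
})

test_that("emergency application reports OR choice and load bound", {
  b <- tiny_bundle("heuristic")
  inst <- b$instance
  H <- emergency_moments(inst)
  for (h in c(0L, 5L, 11L)) {
    ap <- apply_emergency(b, h, 1L, 2L)
    expect_length(ap$or, 1)
    expect_lte(ap$elective_load, ap$load_bound + 1e-9)
    # nobody starting at or before h is displaced
    for (pid in ap$displaced) {
      i <- match(pid, inst$patients$id)
      expect_gt(sum(b$xi[i, 1, ]), h)
    }
  }
  expect_error(apply_emergency(b, 99L, 1L, 1L), "not in the bundle")
})

test_that("no-show application moves the substitute and returns the patient", {
  b <- tiny_bundle("heuristic")
  ns <- nominal_schedule(b)
  day1 <- ns$patient[ns$day == 1]
  for (pid in day1) {
    ap <- apply_noshow(b, pid, 1L)
    expect_equal(ap$return_day, 1L + b$instance$delta_noshow)
    expect_true(all(ap$day_load <= ap$load_bound + 1e-9))
    # the substitute appears exactly once in the plan
    expect_equal(sum(ap$assignments$patient == ap$substitute), 1)
  }
  expect_error(apply_noshow(b, "P2", 1L), "not nominally scheduled")
})

test_that("gantt rendering has one row per OR with slot-width cells", {
  b <- tiny_bundle("heuristic")
  lines <- utils::capture.output(g <- render_gantt(b, day = 1))
  expect_equal(sum(grepl("^OR", g)), b$instance$num_ors)
  width <- nchar(sub("^OR\\d+ \\|", "", sub("\\|$", "", g[1])))
  expect_equal(width, b$instance$capacity[1, 1])
})
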