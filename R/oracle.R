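# Exhaustive reference solver for tiny instances.
#
# The oracle never touches the MILP machinery: it enumerates assignments
# directly and evaluates penalties by plain arithmetic, providing ground
# truth for the nominal optimum and for per-scenario restoration-plan
# feasibility/optimality.

.oracle_guard <- function(instance, max_patients = 7L, max_days = 3L,
                          max_ors = 2L) {
  nI <- nrow(instance$patients)
  if (nI > max_patients || instance$horizon_days > max_days ||
      instance$num_ors > max_ors)
    stop("instance exceeds the oracle guard rails (<= ", max_patients,
         " patients, ", max_days, " days, ", max_ors, " ORs)")
  invisible(TRUE)
}

#' Brute-force nominal optimum
#'
#' Enumerates every assignment of each patient to \{unscheduled\} or a
#' compatible (day, OR) pair that respects capacity, and returns the exact
#' minimum of the penalty objective together with all optimal assignments.
#'
#' @param instance a tiny \code{or_instance} (guard rails: at most 7
#'   patients, 3 days, 2 ORs).
#' @param weighting penalty weighting.
#' @return list: \code{objective}, \code{argmins} (list of data.frames
#'   patient/day/or, day 0 = unscheduled), \code{states} enumerated.
#' @export
brute_force_nominal <- function(instance, weighting = "full") {
  .oracle_guard(instance)
  pen <- penalty_table(instance, weighting)
  nI <- nrow(instance$patients)
  nD <- instance$horizon_days; nJ <- instance$num_ors
  t <- instance$patients$duration_slots
  a <- instance$compatibility
  options <- lapply(seq_len(nI), function(i) {
    opts <- list(list(d = 0L, j = 0L, cost = unname(pen$q[i])))
    for (d in seq_len(nD)) for (j in seq_len(nJ))
      if (a[i, d, j] == 1)
        opts[[length(opts) + 1L]] <- list(d = d, j = j, cost = unname(pen$p[i, d]))
    opts
  })
  best <- Inf; argmins <- list(); states <- 0L
  cap <- matrix(instance$capacity, nD, nJ)
  assign <- integer(nI)
  recurse <- function(i, cost) {
    if (i > nI) {
      states <<- states + 1L
      if (cost < best - 1e-9) { best <<- cost; argmins <<- list(assign) }
      else if (abs(cost - best) <= 1e-9)
        argmins[[length(argmins) + 1L]] <<- assign
      return()
    }
    for (k in seq_along(options[[i]])) {
      o <- options[[i]][[k]]
      if (o$d > 0L && cap[o$d, o$j] < t[i]) next
      if (o$d > 0L) cap[o$d, o$j] <<- cap[o$d, o$j] - t[i]
      assign[i] <<- k
      recurse(i + 1L, cost + o$cost)
      if (o$d > 0L) cap[o$d, o$j] <<- cap[o$d, o$j] + t[i]
    }
  }
  recurse(1L, 0)
  args <- lapply(argmins, function(as_) {
    do.call(rbind, lapply(seq_len(nI), function(i) {
      o <- options[[i]][[as_[i]]]
      data.frame(patient = instance$patients$id[i], day = o$d, or = o$j,
                 stringsAsFactors = FALSE)
    }))
  })
  list(objective = best, argmins = args, states = states)
}

# Penalty of a scenario assignment given as integer vectors day[i] (0 =
# excluded) -- shared by the RS oracles.
.scenario_penalty <- function(day, pen) {
  tot <- 0
  for (i in seq_along(day))
    tot <- tot + if (day[i] == 0L) unname(pen$q[i]) else pen$p[i, day[i]]
  tot
}

# Enumerate optimal restoration penalty for one emergency scenario by DFS
# over per-patient choices.  Nominal start times are fixed inputs.
.best_emergency_rs <- function(instance, pen, x, xi, h, g, l, eta_or) {
  nI <- nrow(instance$patients); nD <- instance$horizon_days
  nJ <- instance$num_ors
  t <- instance$patients$duration_slots
  a <- instance$compatibility
  Om <- instance$overtime_slots; Delta <- instance$delta_max
  gam <- instance$emergency_classes[l]
  cap <- matrix(instance$capacity, nD, nJ)
  cut <- min(gam, instance$capacity[g, eta_or] - h)
  cap[g, ] <- cap[g, ] + Om
  cap[g, eta_or] <- cap[g, eta_or] - cut
  nomday <- vapply(seq_len(nI), function(i) {
    d <- which(apply(x[i, , , drop = FALSE], 2, sum) == 1)
    if (length(d)) d else 0L
  }, integer(1))
  nomor <- vapply(seq_len(nI), function(i)
    if (nomday[i] > 0L) which(x[i, nomday[i], ] == 1) else 0L, integer(1))
  opts <- lapply(seq_len(nI), function(i) {
    if (nomday[i] == 0L) return(list(list(d = 0L, j = 0L, cost = 0)))
    movable <- nomday[i] != g || sum(xi[i, g, ]) > h   # starts after h
    if (!movable)
      return(list(list(d = nomday[i], j = nomor[i], cost = pen$p[i, nomday[i]])))
    out <- list()
    # a displaced protected-day patient must reappear before g + Delta; a
    # later-day patient may land on any not-earlier day (beyond its own
    # Delta window the drop flag mu absorbs the window constraint) or be
    # pushed out entirely at the exclusion penalty
    hi <- if (nomday[i] == g) min(nD, g + Delta - 1L) else nD
    for (d in nomday[i]:hi) for (j in seq_len(nJ))
      if (a[i, d, j] == 1)
        out[[length(out) + 1L]] <- list(d = d, j = j, cost = unname(pen$p[i, d]))
    if (nomday[i] != g)
      out[[length(out) + 1L]] <- list(d = 0L, j = 0L, cost = unname(pen$q[i]))
    out
  })
  best <- Inf
  recurse <- function(i, cost) {
    if (cost >= best - 1e-9) return()
    if (i > nI) { best <<- cost; return() }
    for (o in opts[[i]]) {
      if (o$d > 0L) {
        if (cap[o$d, o$j] < t[i]) next
        cap[o$d, o$j] <<- cap[o$d, o$j] - t[i]
      }
      recurse(i + 1L, cost + o$cost)
      if (o$d > 0L) cap[o$d, o$j] <<- cap[o$d, o$j] + t[i]
    }
  }
  recurse(1L, 0)
  # exclusion penalties of never-scheduled patients are a constant addend
  best + sum(pen$q[nomday == 0L])
}

# Optimal restoration penalty for one no-show scenario, given the
# designated substitutes (theta) -- per-patient DFS as above.
.best_noshow_rs <- function(instance, pen, x, b, g, theta,
                            noshow_mode = "fixed_delay") {
  nI <- nrow(instance$patients); nD <- instance$horizon_days
  nJ <- instance$num_ors
  t <- instance$patients$duration_slots
  a <- instance$compatibility
  Om <- instance$overtime_slots; Dh <- instance$delta_noshow
  cap <- matrix(instance$capacity, nD, nJ)
  cap[g, ] <- cap[g, ] + Om
  nomday <- vapply(seq_len(nI), function(i) {
    d <- which(apply(x[i, , , drop = FALSE], 2, sum) == 1)
    if (length(d)) d else 0L
  }, integer(1))
  nomor <- vapply(seq_len(nI), function(i)
    if (nomday[i] > 0L) which(x[i, nomday[i], ] == 1) else 0L, integer(1))
  if (nomday[b] != g) return(NA_real_)       # vacuous scenario
  jb <- nomor[b]
  sub <- which(theta[, g, jb] == 1)
  opts <- lapply(seq_len(nI), function(i) {
    if (nomday[i] == 0L) return(list(list(d = 0L, j = 0L, cost = 0))) # stays out
    if (i == b) {
      out <- list()
      days_b <- if (noshow_mode == "fixed_delay") g + Dh
                else seq(g, min(nD, g + instance$delta_max - 1L))
      for (d in days_b) for (j in seq_len(nJ))
        if (d <= nD && a[i, d, j] == 1)
          out[[length(out) + 1L]] <- list(d = d, j = j, cost = unname(pen$p[i, d]))
      return(out)
    }
    if (nomday[i] == g)                       # retained in place (49)
      return(list(list(d = g, j = nomor[i], cost = unname(pen$p[i, g]))))
    if (length(sub) && i == sub) {            # activated substitute: day g or stay
      out <- list(list(d = g, j = jb, cost = unname(pen$p[i, g])))
      for (d in nomday[i]:nD) for (j in seq_len(nJ))
        if (a[i, d, j] == 1)
          out[[length(out) + 1L]] <- list(d = d, j = j, cost = unname(pen$p[i, d]))
      return(out)
    }
    out <- list(list(d = 0L, j = 0L, cost = unname(pen$q[i])))   # may be pushed out
    for (d in nomday[i]:nD) for (j in seq_len(nJ))
      if (a[i, d, j] == 1)
        out[[length(out) + 1L]] <- list(d = d, j = j, cost = unname(pen$p[i, d]))
    out
  })
  if (any(lengths(opts) == 0L)) return(Inf)   # scenario infeasible
  # substitute obligation: x-hat[sub, g, jb] = 1 (eq40)
  best <- Inf
  recurse <- function(i, cost) {
    if (cost >= best - 1e-9) return()
    if (i > nI) { best <<- cost; return() }
    for (o in opts[[i]]) {
      if (length(sub) && i == sub && !(o$d == g && o$j == jb)) next
      if (o$d > 0L) {
        if (cap[o$d, o$j] < t[i]) next
        cap[o$d, o$j] <<- cap[o$d, o$j] - t[i]
      }
      recurse(i + 1L, cost + o$cost)
      if (o$d > 0L) cap[o$d, o$j] <<- cap[o$d, o$j] + t[i]
    }
  }
  recurse(1L, 0)
  best + sum(pen$q[nomday == 0L])
}

#' Exhaustive restoration-plan check for a bundle
#'
#' For every emergency scenario, re-derives by enumeration the optimal
#' restoration penalty given the bundle's nominal schedule and first-
#' available OR choice, and compares it with the bundle's plan; likewise
#' for no-show scenarios given the bundle's designated substitutes.
#'
#' @param bundle a \code{schedule_bundle} from the pipeline.
#' @param check_optimal also require the bundle's per-scenario penalties to
#'   match the enumerated optima (use when the plan steps solved to
#'   optimality).
#' @return list: \code{ok}, \code{emergency} and \code{noshow} data.frames
#'   with per-scenario bundle vs. oracle penalties.
#' @export
exhaustive_rs_check <- function(bundle, check_optimal = TRUE) {
  inst <- bundle$instance
  .oracle_guard(inst)
  pen <- penalty_table(inst, bundle$config$penalty_weighting %||% "full")
  H <- emergency_moments(inst)
  nL <- length(inst$emergency_classes)
  ids <- inst$patients$id
  em <- list()
  for (hh in seq_along(H)) for (g in seq_len(inst$rs_days)) for (l in seq_len(nL)) {
    eta_or <- which(bundle$eta[hh, g, ] == 1)
    arr <- bundle$xbar[hh, g, l, , , , drop = FALSE]
    dim(arr) <- dim(bundle$xbar)[4:6]
    got <- .scenario_penalty(
      vapply(seq_len(nrow(inst$patients)), function(i) {
        d <- which(apply(arr[i, , , drop = FALSE], 2, sum) == 1)
        if (length(d)) d else 0L
      }, integer(1)), pen)
    opt <- .best_emergency_rs(inst, pen, bundle$x, bundle$xi,
                              H[hh], g, l, eta_or)
    em[[length(em) + 1L]] <- data.frame(h = H[hh], g = g, l = l,
                                        bundle = got, oracle = opt)
  }
  em <- do.call(rbind, em)
  ns <- list()
  for (b in seq_along(ids)) for (g in seq_len(inst$rs_days)) {
    if (sum(bundle$x[b, g, ]) < 0.5) next
    arr <- bundle$xhat[b, g, , , , drop = FALSE]
    dim(arr) <- dim(bundle$xhat)[3:5]
    got <- .scenario_penalty(
      vapply(seq_len(nrow(inst$patients)), function(i) {
        d <- which(apply(arr[i, , , drop = FALSE], 2, sum) == 1)
        if (length(d)) d else 0L
      }, integer(1)), pen)
    opt <- .best_noshow_rs(inst, pen, bundle$x, b, g, bundle$theta,
                           bundle$noshow_mode)
    ns[[length(ns) + 1L]] <- data.frame(b = ids[b], g = g,
                                        bundle = got, oracle = opt)
  }
  ns <- if (length(ns)) do.call(rbind, ns) else
    data.frame(b = character(0), g = integer(0), bundle = numeric(0),
               oracle = numeric(0))
  feas <- all(is.finite(em$bundle)) && all(em$bundle >= em$oracle - 1e-6) &&
    (nrow(ns) == 0L || all(ns$bundle >= ns$oracle - 1e-6))
  ok <- feas && (!check_optimal ||
                   (all(abs(em$bundle - em$oracle) < 1e-6) &&
                      (nrow(ns) == 0L || all(abs(ns$bundle - ns$oracle) < 1e-6))))
  list(ok = ok, emergency = em, noshow = ns)
}
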