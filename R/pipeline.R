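# Sequential solution procedure.
#
# Step 1   solve the nominal assignment problem (Block A, penalty objective);
#          store x*.
# Steps 3-4 (warm start)  solve the complete model under the penalty
#          objective with the protected-day admissions of x* pinned
#          (Block ii).  The backend takes no incumbent hints, so the pin is
#          applied before the solve -- the documented fallback realization
#          of the warm start.
# Steps 5-6 (heuristic)   solve the complete model minimizing the number of
#          patient-day differences from x* (Block i, difference objective),
#          then pin the protected-day admissions of that solution (Block ii)
#          and re-solve under the penalty objective.
# Step 7   freeze the full nominal assignment and optimize the emergency
#          restoration plans (scenario-averaged penalty objective); the
#          solve also decides the within-day ordering.
# Step 8   fix the ordering and OR assignment (Block iii).
# Step 9   optimize the no-show restoration plans.
#
# Emergencies are optimized strictly before no-shows: ordering must be
# settled to place emergencies, and ordering does not affect no-show
# management.

#' Pipeline configuration
#'
#' @param strategy \code{"heuristic"} or \code{"warm_start"}.
#' @param time_limit per-step backend time limit, seconds (benchmark default
#'   900 s; scale down for small studies).
#' @param gap relative MIP gap tolerance per step.
#' @param noshow_mode \code{"fixed_delay"} or \code{"window"}; see
#'   \code{\link{build_complete_model}}.
#' @param eq29_window see \code{\link{build_complete_model}}.
#' @param penalty_weighting see \code{\link{penalty_table}}.
#' @param noshow_norm optional override of the no-show objective scaling.
#' @param allow_dummy_substitute when TRUE, a sentinel patient of minimal
#'   (one-slot) duration, compatible everywhere, is appended so that a
#'   designated substitute always exists even on degenerate instances.
#' @param verbose print backend logs.
#' @export
solve_config <- function(strategy = c("heuristic", "warm_start"),
                         time_limit = 900, gap = 1e-4,
                         noshow_mode = c("fixed_delay", "window"),
                         eq29_window = c("printed", "rs_day"),
                         penalty_weighting = c("full", "tardiness_only"),
                         noshow_norm = NULL,
                         allow_dummy_substitute = FALSE,
                         verbose = FALSE) {
  structure(list(strategy = match.arg(strategy), time_limit = time_limit,
                 gap = gap, noshow_mode = match.arg(noshow_mode),
                 eq29_window = match.arg(eq29_window),
                 penalty_weighting = match.arg(penalty_weighting),
                 noshow_norm = noshow_norm,
                 allow_dummy_substitute = allow_dummy_substitute,
                 verbose = verbose),
            class = "solve_config")
}

.metric <- function(sol) list(objective = sol$objective, bound = sol$bound,
                              gap = sol$gap, status = sol$status,
                              seconds = sol$seconds)

#' Step 1: solve the nominal problem
#'
#' @param instance an \code{or_instance}.
#' @param config a \code{\link{solve_config}}.
#' @return list with the assignment array \code{x_star}, \code{objective},
#'   \code{bound}, \code{status} and the penalty table used.
#' @export
solve_nominal <- function(instance, config = solve_config()) {
  pen <- penalty_table(instance, config$penalty_weighting)
  m <- build_nominal_model(instance, pen)
  # the penalty objective carries the large additive constant sum(q), which
  # makes the backend's relative gap on the raw objective meaninglessly
  # loose on the true scale; the nominal model is small, so always solve it
  # (effectively) to optimality
  sol <- solve_model(m, config$time_limit, min(config$gap, 1e-6),
                     config$verbose)
  if (is.null(sol$x)) stop("nominal solve found no incumbent: ", sol$status)
  list(x_star = solution_values(m, sol, "x"), objective = sol$objective,
       bound = sol$bound, status = sol$status, gap = sol$gap,
       seconds = sol$seconds, penalties = pen)
}

.fix_family <- function(m, name, values) {
  fam <- m$vars[[name]]
  ids <- fam$offset + seq_len(prod(fam$dim))
  m$lb[ids] <- as.vector(values)
  m$ub[ids] <- as.vector(values)
  invisible(m)
}

.with_dummy <- function(instance, config) {
  if (!isTRUE(config$allow_dummy_substitute)) return(instance)
  p <- instance$patients
  sentinel <- p[1, , drop = FALSE]
  sentinel$id <- "SENTINEL"
  sentinel$duration_slots <- 1L
  sentinel$deadline_days <- 360L
  sentinel$waited_days <- 0L
  a <- array(1L, dim = c(1L, instance$horizon_days, instance$num_ors))
  inst2 <- instance
  inst2$patients <- rbind(p, sentinel)
  comp <- array(0L, dim = dim(instance$compatibility) + c(1L, 0L, 0L))
  comp[seq_len(nrow(p)), , ] <- instance$compatibility
  comp[nrow(p) + 1L, , ] <- a
  inst2$compatibility <- comp
  inst2
}

# Deterministic decongestion of a nominal assignment: when every day of
# the emergency-recovery window (g+1 .. g+Delta-1) is packed, no feasible
# restoration plan exists for long emergencies and the x-fixed probe is
# provably infeasible.  Relocate patients out of the window -- cheapest
# penalty increase first, never touching the protected day itself, so
# Block-ii pinning stays satisfied -- until the window holds at least
# max(gamma) + overtime free slots.  Returns x unchanged if already slack.
.decongest <- function(instance, x_star, max_moves = 60L) {
  x <- x_star
  t <- instance$patients$duration_slots
  a <- instance$compatibility
  Tc <- instance$capacity
  pen <- penalty_table(instance)
  nD <- instance$horizon_days; nJ <- instance$num_ors
  target <- max(instance$emergency_classes) + instance$overtime_slots
  for (g in seq_len(instance$rs_days)) {
    wend <- min(g + instance$delta_max - 1L, nD)
    if (g + 1L > wend || wend >= nD) next      # no window or no room after it
    win <- seq(g + 1L, wend)
    for (iter in seq_len(max_moves)) {
      load <- vapply(seq_len(nD), function(d)
        sum(vapply(seq_len(nJ), function(j) sum(t * x[, d, j]), numeric(1))),
        numeric(1))
      # usable capacity only: a weekend day blocked for everyone offers no
      # displacement room however empty it is
      cap_d <- vapply(seq_len(nD), function(d)
        sum(vapply(seq_len(nJ), function(j)
          if (any(a[, d, j] == 1)) Tc[d, j] else 0L, numeric(1))),
        numeric(1))
      if (sum(cap_d[win] - load[win]) >= target) break
      donor <- win[which.min(cap_d[win] - load[win])]
      cands <- which(apply(x[, donor, , drop = FALSE], 1, sum) == 1)
      best <- NULL
      for (i in cands) for (e in seq(wend + 1L, nD))
        for (j in seq_len(nJ)) {
          if (a[i, e, j] != 1) next
          if (Tc[e, j] - sum(t * x[, e, j]) < t[i]) next
          dcost <- pen$p[i, e] - pen$p[i, donor]
          if (is.null(best) || dcost < best$dcost)
            best <- list(i = i, e = e, j = j, dcost = dcost)
        }
      if (is.null(best)) break
      jold <- which(x[best$i, donor, ] == 1)
      x[best$i, donor, jold] <- 0
      x[best$i, best$e, best$j] <- 1
    }
  }
  .stage_substitutes(instance, x)
}

# Second repair phase: every OR of a protected day needs a designated
# substitute from day g+1 that is short enough to cover even the shortest
# no-show on that OR within the overtime allowance:
#   t_sub <= min_b t_b + T_gj + Omega - load_gj.
# When no admissible day-(g+1) candidate exists, stage one: pull a short
# patient from a later day onto day g+1 (evicting the longest day-(g+1)
# patient to a later day first if room is needed).
.stage_substitutes <- function(instance, x, max_fix = 10L) {
  t <- instance$patients$duration_slots
  a <- instance$compatibility
  Tc <- instance$capacity
  nI <- length(t); nD <- instance$horizon_days; nJ <- instance$num_ors
  Om <- instance$overtime_slots
  day_of <- function(x, i) {
    d <- which(apply(x[i, , , drop = FALSE], 2, sum) == 1)
    if (length(d)) d else 0L
  }
  free <- function(x, d, j) Tc[d, j] - sum(t * x[, d, j])
  move_to <- function(x, i, e, j) {
    d0 <- day_of(x, i)
    x[i, d0, which(x[i, d0, ] == 1)] <- 0
    x[i, e, j] <- 1
    x
  }
  for (g in seq_len(instance$rs_days)) {
    if (g + 1L > nD) next
    for (fix in seq_len(max_fix)) {
      days <- vapply(seq_len(nI), function(i) day_of(x, i), integer(1))
      need <- vapply(seq_len(nJ), function(j) {
        onj <- which(days == g & x[, g, j] == 1)
        if (!length(onj)) return(Inf)
        min(t[onj]) + Tc[g, j] + Om - sum(t * x[, g, j])
      }, numeric(1))
      cands <- which(days == g + 1L)
      # greedy distinct matching, tightest OR first, shortest candidate first
      ord <- order(need)
      used <- integer(0); unmatched <- integer(0)
      for (j in ord) {
        ok <- cands[t[cands] <= need[j] & a[cands, g, j] == 1 &
                      !(cands %in% used)]
        if (length(ok)) used <- c(used, ok[which.min(t[ok])])
        else unmatched <- c(unmatched, j)
      }
      if (!length(unmatched)) break
      j <- unmatched[1]
      compat_g1 <- apply(a[, g + 1L, , drop = FALSE], 1, sum) > 0
      movers <- which(days > g + 1L & t <= need[j] & a[, g, j] == 1 &
                        compat_g1)
      movers <- setdiff(movers, used)
      if (!length(movers)) break
      i <- movers[which.min(t[movers])]
      dest <- which(vapply(seq_len(nJ), function(jj)
        a[i, g + 1L, jj] == 1 && free(x, g + 1L, jj) >= t[i], logical(1)))
      if (!length(dest)) {
        # evict the longest non-candidate day-(g+1) patient to a later day
        evictable <- setdiff(cands, used)
        if (!length(evictable)) break
        ev <- evictable[which.max(t[evictable])]
        spot <- NULL
        for (e in seq(g + 2L, nD)) for (jj in seq_len(nJ))
          if (is.null(spot) && a[ev, e, jj] == 1 && free(x, e, jj) >= t[ev])
            spot <- c(e, jj)
        if (is.null(spot)) break
        x <- move_to(x, ev, spot[1], spot[2])
        dest <- which(vapply(seq_len(nJ), function(jj)
          a[i, g + 1L, jj] == 1 && free(x, g + 1L, jj) >= t[i], logical(1)))
        if (!length(dest)) break
      }
      x <- move_to(x, i, g + 1L, dest[1])
    }
  }
  x
}

# Probe-then-solve: the feasible region of the complete model is contained
# in the nominal one, so any complete solution whose objective matches the
# nominal optimum is provably optimal.  The probe fixes the assignment to a
# reference x and solves the (much easier) residual problem; when feasible
# and matching the bound hint, the expensive cold solve is skipped -- the
# backend accepts no incumbent hints, so this is how a warm start is
# realized.  When the probe is infeasible or insufficient, the full model
# is solved cold and the better incumbent wins.
.solve_with_probe <- function(m, x_probe, config, accept_hint = -Inf,
                              valid_bound = NULL) {
  fam <- m$vars[["x"]]
  ids <- fam$offset + seq_len(prod(fam$dim))
  run_fixed <- function(xv) {
    old_lb <- m$lb[ids]; old_ub <- m$ub[ids]
    m$lb[ids] <- as.vector(xv); m$ub[ids] <- as.vector(xv)
    # the probe gets the full per-step budget (at least 60 s, as a margin
    # against slow machines): when it succeeds at the bound hint the cold
    # solve is skipped entirely, and infeasibility of the fixed assignment
    # is normally proven quickly
    res <- solve_model(m, max(60, config$time_limit), config$gap,
                       config$verbose)
    m$lb[ids] <- old_lb; m$ub[ids] <- old_ub
    res
  }
  probe <- run_fixed(x_probe)
  if (is.null(probe$x)) {
    # congested reference: relocate patients out of the recovery window and
    # retry (never moves protected-day patients, so Block-ii pins survive)
    x2 <- .decongest(m$instance, x_probe)
    if (!identical(x2, x_probe)) {
      probe <- run_fixed(x2)
      if (!is.null(probe$x)) probe$status <- "probe_decongested"
    }
  }
  if (!is.null(probe$x) && is.finite(accept_hint) &&
      probe$objective <= accept_hint + 1e-6) {
    # any incumbent at the nominal-problem incumbent value is optimal up to
    # the step-1 gap; the nominal lower bound remains valid here
    probe$bound <- if (!is.null(valid_bound) && is.finite(valid_bound))
      valid_bound else probe$objective
    probe$gap <- if (probe$bound != 0)
      (probe$objective - probe$bound) / abs(probe$bound) else 0
    probe$status <- "optimal"
    return(probe)
  }
  main <- solve_model(m, config$time_limit, config$gap, config$verbose)
  if (is.null(main$x)) {
    if (is.null(probe$x)) return(main)
    probe$status <- "probe_only"
    if (is.finite(main$bound %||% NA_real_)) probe$bound <- main$bound
    return(probe)
  }
  if (!is.null(probe$x) && probe$objective < main$objective - 1e-9) {
    probe$bound <- main$bound
    probe$status <- main$status
    return(probe)
  }
  main
}

#' Steps 3-4: warm-start route to a complete feasible solution
#'
#' The protected-day admissions of the nominal solution are pinned (Block
#' ii) and the complete model is solved, seeding the search by first
#' probing the nominal assignment itself (see Details in the package
#' vignette: the backend takes no incumbent hints, so the warm start is
#' realized by probe-and-pin).
#'
#' @param instance an \code{or_instance}.
#' @param x_star nominal assignment array from \code{\link{solve_nominal}}.
#' @param config a \code{\link{solve_config}}.
#' @param bound_hint lower bound of the nominal problem (used to recognize
#'   a provably optimal probe).
#' @return internal pipeline state (model, incumbent, metrics).
#' @export
run_warm_start <- function(instance, x_star, config = solve_config("warm_start"),
                           bound_hint = -Inf, valid_bound = NULL) {
  pen <- penalty_table(instance, config$penalty_weighting)
  m <- build_complete_model(instance, pen, config$noshow_mode, config$eq29_window)
  attach_auxiliary_block(m, "ii", x_star)
  set_objective(m, "nominal")
  sol <- .solve_with_probe(m, x_star, config, bound_hint, valid_bound)
  if (is.null(sol$x))
    stop("warm start found no complete incumbent (status ", sol$status,
         "); consider the heuristic strategy or a larger time limit")
  list(model = m, sol = sol,
       metrics = list(complete = .metric(sol)))
}

#' Steps 5-6: sequential heuristic route
#'
#' @inheritParams run_warm_start
#' @return internal pipeline state (model, incumbent, metrics).
#' @export
run_heuristic <- function(instance, x_star, config = solve_config("heuristic"),
                          bound_hint = -Inf, valid_bound = NULL) {
  pen <- penalty_table(instance, config$penalty_weighting)
  m <- build_complete_model(instance, pen, config$noshow_mode, config$eq29_window)
  attach_auxiliary_block(m, "i", x_star)
  set_objective(m, "difference")
  # a zero-difference solution (x = x*) is optimal whenever feasible
  sol5 <- .solve_with_probe(m, x_star, config, accept_hint = 0, valid_bound = 0)
  if (is.null(sol5$x))
    stop("heuristic difference step found no incumbent (status ",
         sol5$status, ")")
  x5 <- solution_values(m, sol5, "x")
  attach_auxiliary_block(m, "ii", x5)
  set_objective(m, "nominal")
  sol6 <- .solve_with_probe(m, x5, config, bound_hint, valid_bound)
  if (is.null(sol6$x))
    stop("heuristic re-optimization step found no incumbent (status ",
         sol6$status, ")")
  list(model = m, sol = sol6,
       metrics = list(difference = .metric(sol5), complete = .metric(sol6)))
}

# Plan-optimization solves, in three tiers of restriction:
#   probe  -- every binary fixed to a known feasible reference: an LP, so an
#             incumbent is always recovered;
#   restricted -- the families in `restrict` (typically the within-day
#             ordering) fixed to the reference: the scenario subproblems
#             decouple and the backend optimizes the plans quickly;
#   full   -- nothing fixed; attempted only under a generous time budget
#             (> 120 s per step), since cold incumbent-finding on the
#             complete model routinely exhausts small budgets.
# The best incumbent wins.
.solve_with_fallback <- function(m, ref_x, config, restrict = character(0)) {
  binids <- which(m$vtype == "B")
  old_lb <- m$lb[binids]; old_ub <- m$ub[binids]
  vals <- round(ref_x[binids])
  m$lb[binids] <- vals; m$ub[binids] <- vals
  best <- solve_model(m, max(30, 0.3 * config$time_limit), config$gap,
                      config$verbose)
  best$status <- if (is.null(best$x)) best$status else "probe_only"
  m$lb[binids] <- old_lb; m$ub[binids] <- old_ub

  consider <- function(best, cand, status) {
    if (is.null(cand$x)) return(best)
    cand$status <- status
    if (is.null(best$x) || cand$objective <= best$objective + 1e-9) cand
    else best
  }
  if (length(restrict)) {
    save <- list()
    for (fam in restrict) {
      f <- m$vars[[fam]]
      ids <- f$offset + seq_len(prod(f$dim))
      save[[fam]] <- list(ids = ids, lb = m$lb[ids], ub = m$ub[ids])
      v <- round(ref_x[ids])
      m$lb[ids] <- v; m$ub[ids] <- v
    }
    res <- solve_model(m, config$time_limit, config$gap, config$verbose)
    for (s in save) { m$lb[s$ids] <- s$lb; m$ub[s$ids] <- s$ub }
    best <- consider(best, res,
                     if (res$status == "optimal") "optimal_fixed_order"
                     else res$status)
  }
  if (config$time_limit > 120 || !length(restrict)) {
    res <- solve_model(m, config$time_limit, config$gap, config$verbose)
    best <- consider(best, res, res$status)
    if (!is.null(best$x) && is.finite(res$bound %||% NA_real_))
      best$bound <- res$bound
  }
  best
}

#' Steps 7-9: optimize the restoration plans
#'
#' Freezes the nominal assignment of the supplied state, optimizes the
#' emergency plans (which also settles the within-day ordering), fixes the
#' ordering, then optimizes the no-show plans.  Emergency plans are frozen
#' during Step 9: once the nominal schedule is fixed the two plan sets do
#' not interact, so this is a pure model reduction.
#'
#' @param state pipeline state from \code{\link{run_warm_start}} or
#'   \code{\link{run_heuristic}}.
#' @param config a \code{\link{solve_config}}.
#' @return a \code{schedule_bundle}.
#' @export
optimize_backup_plans <- function(state, config = solve_config()) {
  m <- state$model
  if (is.null(m$vars[["y"]])) stop("state has no ordering variables")
  .fix_family(m, "x", solution_values(m, state$sol, "x"))
  set_objective(m, "emergency")
  sol7 <- .solve_with_fallback(m, state$sol$x, config,
                               restrict = c("y", "nu", "rho", "lam"))
  if (is.null(sol7$x)) stop("emergency plan step found no incumbent")
  y_star <- solution_values(m, sol7, "y")
  attach_auxiliary_block(m, "iii", y_star)
  for (fam in c("xbar", "mu", "chi", "eta", "rho", "lam"))
    .fix_family(m, fam, solution_values(m, sol7, fam))
  set_objective(m, "noshow", noshow_norm = config$noshow_norm)
  sol9 <- .solve_with_fallback(m, sol7$x, config)
  if (is.null(sol9$x)) stop("no-show plan step found no incumbent")
  metrics <- c(state$metrics,
               list(emergency = .metric(sol7), noshow = .metric(sol9)))
  bundle <- bundle_from_solution(m, sol9, metrics = metrics, config = config)
  bundle <- repair_dropped_patients(bundle)
  bundle
}

#' Repair unjustified drop flags in emergency plans
#'
#' At coarse MIP gaps the plan optimizer may leave a patient flagged as
#' dropped although room exists inside their recovery window.  Exclusion is
#' always costlier than any in-horizon assignment, so placing such patients
#' greedily (earliest feasible day, then lowest OR index) strictly improves
#' the emergency objective while preserving feasibility of every
#' constraint block.  Deterministic; a no-op on exactly solved plans.
#'
#' @param bundle a \code{schedule_bundle}.
#' @return the repaired bundle, with the emergency objective metric
#'   re-evaluated arithmetically when anything changed.
#' @export
repair_dropped_patients <- function(bundle) {
  inst <- bundle$instance
  t <- inst$patients$duration_slots
  a <- inst$compatibility
  Tc <- inst$capacity
  H <- emergency_moments(inst)
  gam <- inst$emergency_classes
  Om <- inst$overtime_slots; Delta <- inst$delta_max
  nD <- inst$horizon_days; nJ <- inst$num_ors
  dmx <- dim(bundle$xbar)
  changed <- FALSE
  for (hh in seq_len(dmx[1])) for (g in seq_len(dmx[2])) for (l in seq_len(dmx[3])) {
    drops <- which(bundle$mu[hh, g, l, ] == 1)
    for (i in drops) {
      if (sum(bundle$x[i, , ]) < 0.5) { bundle$mu[hh, g, l, i] <- 0; next }
      if (sum(bundle$xbar[hh, g, l, i, , ]) > 0.5) {
        bundle$mu[hh, g, l, i] <- 0; next       # placed anyway: flag stale
      }
      d0 <- which(apply(bundle$x[i, , , drop = FALSE], 2, sum) == 1)
      placed <- FALSE
      for (k in d0:min(d0 + Delta, nD)) {
        if (placed) break
        for (j in seq_len(nJ)) {
          if (a[i, k, j] != 1) next
          cap <- Tc[k, j] - sum(t * bundle$xbar[hh, g, l, , k, j])
          if (k == g) cap <- cap + Om -
              (if (bundle$eta[hh, g, j] == 1) min(gam[l], Tc[g, j] - H[hh]) else 0)
          if (cap >= t[i]) {
            bundle$xbar[hh, g, l, i, k, j] <- 1
            bundle$mu[hh, g, l, i] <- 0
            placed <- TRUE; changed <- TRUE
            break
          }
        }
      }
    }
  }
  if (changed && !is.null(bundle$metrics$emergency)) {
    bundle$metrics$emergency$objective <- evaluate_objective(bundle, "emergency")
    bundle$metrics$emergency$status <-
      paste0(bundle$metrics$emergency$status, "+mu_repair")
  }
  bundle
}

#' Full solution procedure: nominal solve, strategy, back-up plans
#'
#' @param instance an \code{or_instance}.
#' @param config a \code{\link{solve_config}}.
#' @return a \code{schedule_bundle}; see \code{\link{bundle_from_solution}}.
#' @examples
#' \dontrun{
#' inst <- generate_instance(generator_config(n_patients = 20, seed = 1))
#' bundle <- full_pipeline(inst, solve_config("heuristic", time_limit = 60))
#' }
#' @export
full_pipeline <- function(instance, config = solve_config()) {
  instance <- .with_dummy(instance, config)
  step1 <- solve_nominal(instance, config)
  state <- if (config$strategy == "warm_start")
    run_warm_start(instance, step1$x_star, config,
                   bound_hint = step1$objective, valid_bound = step1$bound)
  else run_heuristic(instance, step1$x_star, config,
                     bound_hint = step1$objective, valid_bound = step1$bound)
  state$metrics <- c(list(nominal = list(objective = step1$objective,
                                         bound = step1$bound, gap = step1$gap,
                                         status = step1$status,
                                         seconds = step1$seconds)),
                     state$metrics)
  bundle <- optimize_backup_plans(state, config)
  bundle$strategy <- config$strategy
  bundle
}

# ---- bundle ----------------------------------------------------------------

#' Assemble a schedule bundle from a solved complete model
#'
#' A bundle carries the nominal schedule (assignment, ordering, start
#' slots), the designated substitutes, one emergency restoration plan per
#' (moment, protected day, length class) scenario, one no-show plan per
#' (patient, protected day) scenario, and per-step solver metrics.
#'
#' @param m the solved \code{milp_model}.
#' @param sol an incumbent \code{milp_solution}.
#' @param metrics named list of per-step metrics.
#' @param config the \code{solve_config} used.
#' @return a \code{schedule_bundle}.
#' @export
bundle_from_solution <- function(m, sol, metrics = list(), config = NULL) {
  inst <- m$instance
  b <- list(instance = inst,
            x = solution_values(m, sol, "x"),
            y = solution_values(m, sol, "y"),
            xi = solution_values(m, sol, "xi", round = FALSE),
            C = solution_values(m, sol, "C", round = FALSE),
            eta = solution_values(m, sol, "eta"),
            chi = solution_values(m, sol, "chi"),
            xbar = solution_values(m, sol, "xbar"),
            mu = solution_values(m, sol, "mu"),
            theta = solution_values(m, sol, "theta"),
            xhat = solution_values(m, sol, "xhat"),
            noshow_mode = m$noshow_mode %||% "fixed_delay",
            metrics = metrics, config = config)
  class(b) <- "schedule_bundle"
  b
}

#' Nominal schedule of a bundle as a data.frame
#'
#' @param bundle a \code{schedule_bundle}.
#' @return data.frame with patient, day, or, position, start_slot (start
#'   slots are 1-based and only defined on protected days).
#' @export
nominal_schedule <- function(bundle) {
  inst <- bundle$instance
  idx <- which(bundle$x == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(patient = character(0), day = integer(0),
                      or = integer(0), position = integer(0),
                      start_slot = integer(0)))
  pos <- rep(NA_integer_, nrow(idx)); st <- rep(NA_integer_, nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; d <- idx[r, 2]; j <- idx[r, 3]
    if (d <= inst$rs_days) {
      p <- which(bundle$y[i, d, j, ] == 1)
      if (length(p) == 1L) pos[r] <- p
      st[r] <- as.integer(round(bundle$xi[i, d, j]))
    }
  }
  out <- data.frame(patient = inst$patients$id[idx[, 1]], day = idx[, 2],
                    or = idx[, 3], position = pos, start_slot = st,
                    stringsAsFactors = FALSE)
  out[order(out$day, out$or, out$position, out$start_slot), ]
}

#' Designated substitutes of a bundle
#' @param bundle a \code{schedule_bundle}.
#' @return data.frame with day, or, patient.
#' @export
substitutes <- function(bundle) {
  idx <- which(bundle$theta == 1, arr.ind = TRUE)
  data.frame(day = idx[, 2], or = idx[, 3],
             patient = bundle$instance$patients$id[idx[, 1]],
             stringsAsFactors = FALSE)
}

#' @export
print.schedule_bundle <- function(x, ...) {
  ns <- nominal_schedule(x)
  cat(sprintf("<schedule_bundle> %d scheduled / %d patients; %d emergency + %d no-show plans\n",
              nrow(ns), nrow(x$instance$patients),
              prod(dim(x$xbar)[1:3]), dim(x$xhat)[1] * dim(x$xhat)[2]))
  for (nm in names(x$metrics)) {
    mt <- x$metrics[[nm]]
    cat(sprintf("  %-10s of=%-10.4g bound=%-10.4g status=%s\n",
                nm, mt$objective, mt$bound, mt$status))
  }
  invisible(x)
}

# ---- bundle serialization --------------------------------------------------

.plan_df <- function(assign_arr, ids) {
  idx <- which(assign_arr == 1, arr.ind = TRUE)
  data.frame(patient = ids[idx[, 1]], day = as.integer(idx[, 2]),
             or = as.integer(idx[, 3]), stringsAsFactors = FALSE)
}

#' Write / read a bundle as JSON
#'
#' Day indices are 1-based; emergency moments h are 0-based slot indices;
#' start slots are 1-based.  Emergency plan keys are \code{"h,g,l"}, no-show
#' plan keys \code{"b,g"} (b is the patient id).
#'
#' @param bundle a \code{schedule_bundle}.
#' @param path file path.
#' @param instance the matching \code{or_instance} (for \code{read_bundle}).
#' @return \code{read_bundle} returns a \code{schedule_bundle}.
#' @export
write_bundle <- function(bundle, path) {
  inst <- bundle$instance
  ids <- inst$patients$id
  dmx <- dim(bundle$xbar)
  nH <- dmx[1]; nW <- dmx[2]; nL <- dmx[3]
  em <- list()
  for (h in 1:nH) for (g in 1:nW) for (l in 1:nL) {
    key <- sprintf("%d,%d,%d", h - 1L, g, l)
    arr <- bundle$xbar[h, g, l, , , , drop = FALSE]
    dim(arr) <- dmx[4:6]
    em[[key]] <- list(
      eta_or = as.integer(which(bundle$eta[h, g, ] == 1)),
      impacted = ids[bundle$chi[h, g, ] == 1],
      dropped = ids[bundle$mu[h, g, l, ] == 1],
      assignments = .plan_df(arr, ids))
  }
  dmh <- dim(bundle$xhat)
  ns <- list()
  for (b in seq_len(dmh[1])) for (g in seq_len(dmh[2])) {
    arr <- bundle$xhat[b, g, , , , drop = FALSE]
    dim(arr) <- dmh[3:5]
    ns[[sprintf("%s,%d", ids[b], g)]] <- list(assignments = .plan_df(arr, ids))
  }
  obj <- list(
    conventions = "days 1-based; emergency moments h 0-based; start slots 1-based",
    noshow_mode = bundle$noshow_mode,
    nominal = nominal_schedule(bundle),
    substitutes = substitutes(bundle),
    emergency_plans = em,
    noshow_plans = ns,
    metrics = bundle$metrics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path, instance) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  inst <- instance
  ids <- inst$patients$id
  nI <- length(ids); nD <- inst$horizon_days; nJ <- inst$num_ors
  nW <- inst$rs_days; nH <- length(emergency_moments(inst))
  nL <- length(inst$emergency_classes)
  nS <- max_positions(inst)
  b <- list(instance = inst,
            x = array(0, c(nI, nD, nJ)), y = array(0, c(nI, nW, nJ, nS)),
            xi = array(0, c(nI, nW, nJ)), C = array(0, c(nW, nJ)),
            eta = array(0, c(nH, nW, nJ)), chi = array(0, c(nH, nW, nI)),
            xbar = array(0, c(nH, nW, nL, nI, nD, nJ)),
            mu = array(0, c(nH, nW, nL, nI)),
            theta = array(0, c(nI, nW, nJ)),
            xhat = array(0, c(nI, nW, nI, nD, nJ)),
            noshow_mode = obj$noshow_mode %||% "fixed_delay",
            metrics = obj$metrics, config = NULL)
  nom <- obj$nominal
  for (r in seq_len(NROW(nom))) {
    i <- match(nom$patient[r], ids)
    b$x[i, nom$day[r], nom$or[r]] <- 1
    if (nom$day[r] <= nW) {
      if (!is.na(nom$position[r])) b$y[i, nom$day[r], nom$or[r], nom$position[r]] <- 1
      if (!is.na(nom$start_slot[r])) b$xi[i, nom$day[r], nom$or[r]] <- nom$start_slot[r]
    }
  }
  for (g in 1:nW) for (j in 1:nJ) {
    sel <- b$x[, g, j] == 1
    b$C[g, j] <- if (any(sel))
      max(b$xi[sel, g, j] + inst$patients$duration_slots[sel]) else 0
  }
  sub <- obj$substitutes
  for (r in seq_len(NROW(sub)))
    b$theta[match(sub$patient[r], ids), sub$day[r], sub$or[r]] <- 1
  for (key in names(obj$emergency_plans)) {
    kk <- as.integer(strsplit(key, ",")[[1]])
    h <- kk[1] + 1L; g <- kk[2]; l <- kk[3]
    pl <- obj$emergency_plans[[key]]
    if (length(pl$eta_or)) b$eta[h, g, pl$eta_or] <- 1
    b$chi[h, g, match(unlist(pl$impacted), ids)] <- 1
    b$mu[h, g, l, match(unlist(pl$dropped), ids)] <- 1
    asn <- pl$assignments
    for (r in seq_len(NROW(asn)))
      b$xbar[h, g, l, match(asn$patient[r], ids), asn$day[r], asn$or[r]] <- 1
  }
  for (key in names(obj$noshow_plans)) {
    parts <- strsplit(key, ",")[[1]]
    bi <- match(parts[1], ids); g <- as.integer(parts[2])
    asn <- obj$noshow_plans[[key]]$assignments
    for (r in seq_len(NROW(asn)))
      b$xhat[bi, g, match(asn$patient[r], ids), asn$day[r], asn$or[r]] <- 1
  }
  class(b) <- "schedule_bundle"
  b
}

#' Metrics CSV in the benchmark-table layout
#'
#' One row per run: ID, |D|, |J|, OF (nominal), LB_WS, OF_WS, OF_Heu and
#' the derived price-of-robustness and gap columns.  Either objective
#' column may be NA when only one strategy was run.
#'
#' @param runs list of \code{schedule_bundle}s (or metric lists).
#' @param ids character vector of run labels.
#' @param path output CSV path.
#' @return the data.frame, invisibly.
#' @export
write_metrics_csv <- function(runs, ids, path) {
  rows <- lapply(seq_along(runs), function(k) {
    b <- runs[[k]]
    mt <- if (inherits(b, "schedule_bundle")) b$metrics else b
    strat <- if (inherits(b, "schedule_bundle")) b$strategy %||% "" else ""
    of <- mt$nominal$objective
    ofc <- mt$complete$objective; lbc <- mt$complete$bound
    data.frame(ID = ids[k],
               D = if (inherits(b, "schedule_bundle")) b$instance$horizon_days else NA,
               J = if (inherits(b, "schedule_bundle")) b$instance$num_ors else NA,
               OF = of,
               LB_WS = if (identical(strat, "warm_start")) lbc else NA,
               OF_WS = if (identical(strat, "warm_start")) ofc else NA,
               OF_Heu = if (identical(strat, "heuristic")) ofc else NA,
               price = ofc - of,
               gap_complete = if (!is.null(lbc) && is.finite(lbc) && lbc != 0)
                 (ofc - lbc) / abs(lbc) else NA,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
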