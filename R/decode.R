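# Schedule decoding and solver-independent validation.
#
# Everything here is direct arithmetic on the bundle arrays -- no solver is
# ever consulted.  This module is the trust anchor: a bundle is accepted
# only if every constraint block re-evaluates as satisfied.

#' Decode the per-OR daily schedules of a bundle
#'
#' Start slots are recomputed from the ordering alone (cumulative sum of
#' predecessor durations, plus one) and compared with the stored start
#' times; a mismatch or a gapped/duplicated position sequence is an error.
#'
#' @param bundle a \code{schedule_bundle}.
#' @return nested list \code{[[g]][[j]]} with fields \code{patients}
#'   (ordered indices), \code{ids}, \code{start}, \code{end} (1-based,
#'   exclusive), \code{completion}, \code{idle_tail}.
#' @export
decode_schedule <- function(bundle) {
  inst <- bundle$instance
  t <- inst$patients$duration_slots
  out <- vector("list", inst$rs_days)
  for (g in seq_len(inst$rs_days)) {
    out[[g]] <- vector("list", inst$num_ors)
    for (j in seq_len(inst$num_ors)) {
      sched <- which(bundle$x[, g, j] == 1)
      pos <- integer(length(sched))
      for (k in seq_along(sched)) {
        p <- which(bundle$y[sched[k], g, j, ] == 1)
        if (length(p) != 1L)
          stop("patient ", inst$patients$id[sched[k]],
               " has ", length(p), " positions on day ", g, " OR ", j,
               " (position uniqueness violated)")
        pos[k] <- p
      }
      if (length(pos) && (anyDuplicated(pos) ||
                          !setequal(pos, seq_along(pos))))
        stop("positions on day ", g, " OR ", j,
             " are not the gap-free sequence 1..k (ordering violated)")
      ord <- sched[order(pos)]
      start <- if (length(ord)) cumsum(c(1L, t[ord][-length(ord)])) else integer(0)
      for (k in seq_along(ord)) {
        stored <- round(bundle$xi[ord[k], g, j])
        if (stored != start[k])
          stop("stored start slot ", stored, " of ", inst$patients$id[ord[k]],
               " differs from the ordering-implied start ", start[k])
      }
      comp <- if (length(ord)) start[length(ord)] + t[ord[length(ord)]] else 0L
      out[[g]][[j]] <- list(patients = ord, ids = inst$patients$id[ord],
                            start = start, end = start + t[ord],
                            completion = comp,
                            idle_tail = inst$capacity[g, j] + 1L - comp)
    }
  }
  out
}

# Feasible first-availability values of OR j on day g at 0-based moment h,
# mirroring the model's per-moment machinery including its boundary ties:
# the end of any surgery spanning h (start <= h <= end), plus h itself once
# the OR has emptied.  At h = 0 nothing has started, so every OR counts as
# available immediately.
.avail_set <- function(dec, g, j, h) {
  s <- dec[[g]][[j]]
  if (h == 0) return(0)
  vals <- numeric(0)
  if (length(s$patients))
    vals <- s$end[s$start <= h & h <= s$end]
  if (h >= s$completion) vals <- c(vals, h)
  vals
}

#' First-available-OR check for an emergency assignment
#'
#' Arithmetic re-evaluation of the first-available rule with the model's
#' boundary semantics: the availability of an OR at 0-based moment h is the
#' end of a surgery spanning h, or h itself once the OR has emptied; at a
#' surgery boundary both readings are admissible, and at h = 0 (nothing has
#' started) every OR counts as available immediately.
#'
#' @param bundle a \code{schedule_bundle}.
#' @param h 0-based emergency moment.
#' @param g protected day.
#' @return TRUE iff the plan's chosen OR admits an availability no later
#'   than every other OR's latest admissible availability.
#' @export
emergency_first_available <- function(bundle, h, g = 1L) {
  H <- emergency_moments(bundle$instance)
  hh <- match(h, H)
  et <- which(bundle$eta[hh, g, ] == 1)
  if (length(et) != 1L) return(FALSE)
  if (h == 0) return(TRUE)
  dec <- decode_schedule(bundle)
  feas <- lapply(seq_len(bundle$instance$num_ors),
                 function(j) .avail_set(dec, g, j, h))
  lo_eta <- if (length(feas[[et]])) min(feas[[et]]) else Inf
  hi_all <- vapply(feas, function(f) if (length(f)) max(f) else -Inf,
                   numeric(1))
  lo_eta <= min(hi_all) + 1e-6
}

#' Canonical first availability of each OR at a moment
#'
#' @param bundle a \code{schedule_bundle}.
#' @param h 0-based emergency moment.
#' @param g protected day.
#' @return numeric vector over ORs: \code{h} if the OR has finished, else
#'   the end slot of the surgery in progress.
#' @export
or_availability <- function(bundle, h, g = 1L) {
  dec <- decode_schedule(bundle)
  vapply(seq_len(bundle$instance$num_ors), function(j) {
    s <- dec[[g]][[j]]
    if (h == 0 || h >= s$completion) return(as.numeric(h))
    run <- which(s$start <= h & h < s$end)
    if (length(run)) s$end[run[1]] else as.numeric(h)
  }, numeric(1))
}

.viol <- function(block, eq, index, lhs, rhs) {
  data.frame(block = block, eq = eq, index = index,
             lhs = lhs, rhs = rhs, slack = rhs - lhs,
             stringsAsFactors = FALSE)
}

#' Re-evaluate every constraint block of a bundle arithmetically
#'
#' @param bundle a \code{schedule_bundle}.
#' @param tol integer tolerance (default 1e-6).
#' @return a \code{violation_report}: data.frame of violations (empty when
#'   the bundle is feasible) with a per-block summary attribute.
#' @export
validate_bundle <- function(bundle, tol = 1e-6) {
  inst <- bundle$instance
  t <- inst$patients$duration_slots
  a <- inst$compatibility
  Tc <- inst$capacity
  ids <- inst$patients$id
  nI <- length(ids); nD <- inst$horizon_days; nJ <- inst$num_ors
  nW <- inst$rs_days
  H <- emergency_moments(inst); nH <- length(H)
  gam <- inst$emergency_classes; nL <- length(gam)
  Om <- inst$overtime_slots; Delta <- inst$delta_max; Dh <- inst$delta_noshow
  x <- bundle$x
  v <- list()
  add <- function(...) v[[length(v) + 1L]] <<- .viol(...)

  # Block A
  for (i in 1:nI) {
    s <- sum(x[i, , ])
    if (s > 1 + tol) add("A", "eq4", ids[i], s, 1)
  }
  bad <- which(x > a + tol, arr.ind = TRUE)
  for (r in seq_len(nrow(bad)))
    add("A", "eq5", sprintf("%s,d%d,j%d", ids[bad[r, 1]], bad[r, 2], bad[r, 3]),
        1, 0)
  for (d in 1:nD) for (j in 1:nJ) {
    load <- sum(t * x[, d, j])
    if (load > Tc[d, j] + tol)
      add("A", "eq6", sprintf("d%d,j%d", d, j), load, Tc[d, j])
  }

  # Block B + decode (ordering structure raises errors; convert to violations)
  dec <- tryCatch(decode_schedule(bundle), error = function(e) e)
  if (inherits(dec, "error")) {
    add("B", "eq9/eq10/eq11", "ordering", NA_real_, NA_real_)
    rep <- do.call(rbind, v)
    class(rep) <- c("violation_report", class(rep))
    return(rep)
  }
  for (g in 1:nW) for (j in 1:nJ) {
    s <- dec[[g]][[j]]
    for (k in seq_along(s$patients)) {
      i <- s$patients[k]
      lim <- Tc[g, j] + 1 - t[i]
      if (s$start[k] > lim + tol)
        add("B", "eq15", sprintf("%s,g%d,j%d", ids[i], g, j), s$start[k], lim)
    }
    # the completion variable is pinned from below by the last surgery's end
    # and from above only by the emptiness disjunction at the next integer
    # moment -- which does not exist when the day is (nearly) full, leaving
    # C free above; accept the whole admissible band
    hmax <- max(emergency_moments(inst))
    upper <- if (s$completion + 1 <= hmax) s$completion + 1 else Inf
    if (s$completion > 0 &&
        (bundle$C[g, j] < s$completion - tol ||
         bundle$C[g, j] > upper + tol))
      add("C", "eq16", sprintf("g%d,j%d", g, j), bundle$C[g, j], s$completion)
  }

  # Block D: one OR per emergency, first-available rule (tie-tolerant)
  for (hh in seq_len(nH)) for (g in 1:nW) {
    h <- H[hh]
    et <- which(bundle$eta[hh, g, ] == 1)
    if (length(et) != 1L) {
      add("D", "eq24", sprintf("h%d,g%d", h, g), length(et), 1)
      next
    }
    if (h > 0 && !emergency_first_available(bundle, h, g)) {
      feas <- lapply(1:nJ, function(j) .avail_set(dec, g, j, h))
      lo_eta <- if (length(feas[[et]])) min(feas[[et]]) else Inf
      hi_all <- vapply(feas, function(f) if (length(f)) max(f) else -Inf,
                       numeric(1))
      add("D", "eq25", sprintf("h%d,g%d,j%d", h, g, et), lo_eta, min(hi_all))
    }
  }

  # Blocks E & F: emergency plans
  for (hh in seq_len(nH)) for (g in 1:nW) {
    h <- H[hh]
    for (i in 1:nI) {
      if (bundle$chi[hh, g, i] == 1) {
        st <- sum(bundle$xi[i, g, ])
        if (st < h + inst$epsilon - tol)
          add("E", "eq27", sprintf("h%d,g%d,%s", h, g, ids[i]), st, h + inst$epsilon)
      }
    }
    for (l in 1:nL) {
      xb <- bundle$xbar[hh, g, l, , , , drop = FALSE]
      dim(xb) <- c(nI, nD, nJ)
      for (i in 1:nI) {
        win <- seq_len(min(nD, g + Delta - 1L))
        if (bundle$chi[hh, g, i] == 1 && sum(xb[i, win, ]) < 1 - tol)
          add("E", "eq28", sprintf("h%d,g%d,l%d,%s", h, g, l, ids[i]),
              sum(xb[i, win, ]), 1)
        for (d in 1:nD) {
          kk <- if (identical(bundle$config$eq29_window, "rs_day"))
            intersect(seq(g, min(g + Delta, nD)), d:nD)
          else d:min(d + Delta, nD)
          lhs <- sum(xb[i, kk, ]) + bundle$mu[hh, g, l, i]
          if (lhs < sum(x[i, d, ]) - tol)
            add("E", "eq29", sprintf("h%d,g%d,l%d,%s,d%d", h, g, l, ids[i], d),
                lhs, sum(x[i, d, ]))
        }
        if (sum(xb[i, , ]) > 1 + tol)
          add("F", "eq33", sprintf("h%d,g%d,l%d,%s", h, g, l, ids[i]),
              sum(xb[i, , ]), 1)
        if (sum(xb[i, , ]) > sum(x[i, , ]) + tol)
          add("F", "eq31", sprintf("h%d,g%d,l%d,%s", h, g, l, ids[i]),
              sum(xb[i, , ]), sum(x[i, , ]))
        for (d in 2:nD) {
          lhs <- sum(x[i, d, ]) + sum(xb[i, seq_len(d - 1L), ])
          if (lhs > 1 + tol)
            add("F", "eq30", sprintf("h%d,g%d,l%d,%s,d%d", h, g, l, ids[i], d),
                lhs, 1)
        }
        for (j in 1:nJ) {
          if (xb[i, g, j] < x[i, g, j] - bundle$chi[hh, g, i] - tol)
            add("F", "eq32", sprintf("h%d,g%d,l%d,%s,j%d", h, g, l, ids[i], j),
                xb[i, g, j], x[i, g, j] - bundle$chi[hh, g, i])
        }
        bad <- which(xb[i, , ] > a[i, , ] + tol)
        if (length(bad))
          add("F", "eq34", sprintf("h%d,g%d,l%d,%s", h, g, l, ids[i]), 1, 0)
        # unjustified drop flags: a mu = 1 must be capacity-forced
        if (bundle$mu[hh, g, l, i] == 1 && sum(x[i, , ]) == 1 &&
            sum(xb[i, , ]) == 0) {
          d0 <- which(apply(x[i, , , drop = FALSE], 2, sum) == 1)
          win <- d0:min(d0 + Delta, nD)
          roomy <- FALSE
          for (k in win) for (j in 1:nJ) {
            cap <- Tc[k, j] - sum(t * xb[, k, j])
            if (k == g) cap <- cap + Om -
                (if (bundle$eta[hh, g, j] == 1) min(gam[l], Tc[g, j] - h) else 0)
            if (a[i, k, j] == 1 && cap >= t[i]) roomy <- TRUE
          }
          if (roomy)
            add("F", "mu", sprintf("h%d,g%d,l%d,%s", h, g, l, ids[i]), 1, 0)
        }
      }
      for (j in 1:nJ) {
        for (d in setdiff(1:nD, g)) {
          if (d > g) {
            load <- sum(t * xb[, d, j])
            if (load > Tc[d, j] + tol)
              add("F", "eq35", sprintf("h%d,g%d,l%d,d%d,j%d", h, g, l, d, j),
                  load, Tc[d, j])
          }
        }
        cut <- if (bundle$eta[hh, g, j] == 1) min(gam[l], Tc[g, j] - h) else 0
        load <- sum(t * xb[, g, j])
        if (load > Tc[g, j] - cut + Om + tol)
          add("F", "eq36", sprintf("h%d,g%d,l%d,j%d", h, g, l, j),
              load, Tc[g, j] - cut + Om)
      }
    }
  }

  # Blocks G & H: substitutes and no-show plans
  for (g in 1:nW) {
    for (j in 1:nJ) {
      s <- sum(bundle$theta[, g, j])
      if (abs(s - 1) > tol) add("G", "eq37", sprintf("g%d,j%d", g, j), s, 1)
    }
    for (i in 1:nI) {
      if (sum(bundle$theta[i, g, ]) > sum(x[i, g + 1L, ]) + tol)
        add("G", "eq38", sprintf("%s,g%d", ids[i], g),
            sum(bundle$theta[i, g, ]), sum(x[i, g + 1L, ]))
      for (j in 1:nJ)
        if (bundle$theta[i, g, j] > a[i, g, j] + tol)
          add("G", "eq39", sprintf("%s,g%d,j%d", ids[i], g, j), 1, 0)
    }
    for (b in 1:nI) {
      xh <- bundle$xhat[b, g, , , , drop = FALSE]
      dim(xh) <- c(nI, nD, nJ)
      scheduled_b <- sum(x[b, g, ]) > 0.5
      for (i in 1:nI) for (j in 1:nJ) {
        if (xh[i, g, j] < bundle$theta[i, g, j] + x[b, g, j] - 1 - tol)
          add("G", "eq40", sprintf("%s,g%d,%s,j%d", ids[b], g, ids[i], j),
              xh[i, g, j], bundle$theta[i, g, j] + x[b, g, j] - 1)
      }
      if (bundle$noshow_mode == "fixed_delay") {
        if (scheduled_b && sum(xh[b, g + Dh, ]) < 1 - tol)
          add("G", "eq41", sprintf("%s,g%d", ids[b], g),
              sum(xh[b, g + Dh, ]), 1)
      } else {
        win <- seq_len(min(nD, g + Delta - 1L))
        if (scheduled_b && sum(xh[b, win, ]) < 1 - tol)
          add("G", "eq42", sprintf("%s,g%d", ids[b], g), sum(xh[b, win, ]), 1)
      }
      for (i in 1:nI) {
        if (sum(xh[i, , ]) > 1 + tol)
          add("H", "eq43", sprintf("%s,g%d,%s", ids[b], g, ids[i]),
              sum(xh[i, , ]), 1)
        if (any(xh[i, , ] > a[i, , ] + tol))
          add("H", "eq44", sprintf("%s,g%d,%s", ids[b], g, ids[i]), 1, 0)
        if (sum(xh[i, , ]) > sum(x[i, , ]) + tol)
          add("H", "eq48", sprintf("%s,g%d,%s", ids[b], g, ids[i]),
              sum(xh[i, , ]), sum(x[i, , ]))
        # exemption: i is the designated substitute of an OR on which the
        # no-show b is nominally scheduled
        is_sub <- any(bundle$theta[i, g, ] > 0.5 & x[b, g, ] > 0.5)
        for (d in 2:nD) {
          if (d - 1L >= g + 1L) {
            lhs <- sum(x[i, d, ]) + sum(xh[i, seq(g + 1L, d - 1L), ])
            if (lhs > 1 + tol)
              add("H", "eq47", sprintf("%s,g%d,%s,d%d", ids[b], g, ids[i], d),
                  lhs, 1)
          }
          lhs <- sum(x[i, d, ]) + sum(xh[i, seq_len(min(g, d - 1L)), ])
          if (lhs > 1 + (if (is_sub) 1 else 0) + tol)
            add("H", "eq47b", sprintf("%s,g%d,%s,d%d", ids[b], g, ids[i], d),
                lhs, 1 + (if (is_sub) 1 else 0))
        }
        if (i != b) for (j in 1:nJ) {
          if (xh[i, g, j] < x[i, g, j] - tol)
            add("H", "eq49", sprintf("%s,g%d,%s,j%d", ids[b], g, ids[i], j),
                xh[i, g, j], x[i, g, j])
        }
      }
      for (j in 1:nJ) {
        load <- sum(t * xh[, g, j])
        if (load > Tc[g, j] + Om + tol)
          add("H", "eq46", sprintf("%s,g%d,j%d", ids[b], g, j),
              load, Tc[g, j] + Om)
        for (d in (g + 1L):nD) {
          load <- sum(t * xh[, d, j])
          if (load > Tc[d, j] + tol)
            add("H", "eq45", sprintf("%s,g%d,d%d,j%d", ids[b], g, d, j),
                load, Tc[d, j])
        }
      }
    }
  }

  rep <- if (length(v)) do.call(rbind, v) else
    data.frame(block = character(0), eq = character(0), index = character(0),
               lhs = numeric(0), rhs = numeric(0), slack = numeric(0),
               stringsAsFactors = FALSE)
  attr(rep, "summary") <- if (nrow(rep)) table(rep$eq) else table(character(0))
  class(rep) <- c("violation_report", class(rep))
  rep
}

#' @export
print.violation_report <- function(x, ...) {
  if (nrow(x) == 0L) cat("<violation_report> no violations\n")
  else {
    cat(sprintf("<violation_report> %d violations\n", nrow(x)))
    print(attr(x, "summary"))
    print.data.frame(utils::head(x, 20))
  }
  invisible(x)
}

#' Recompute an objective value from a bundle
#'
#' @param bundle a \code{schedule_bundle}.
#' @param kind \code{"nominal"} (penalties of the nominal assignment),
#'   \code{"emergency"} (scenario-average over emergency plans), or
#'   \code{"noshow"} (scaled average over no-show plans).
#' @param weighting penalty weighting, as in \code{\link{penalty_table}}.
#' @param noshow_norm optional override of the no-show scaling.
#' @return numeric objective value.
#' @export
evaluate_objective <- function(bundle, kind = c("nominal", "emergency", "noshow"),
                               weighting = "full", noshow_norm = NULL) {
  kind <- match.arg(kind)
  inst <- bundle$instance
  pen <- penalty_table(inst, weighting)
  p <- pen$p; q <- pen$q
  nI <- nrow(inst$patients); nD <- inst$horizon_days
  pen_of <- function(assign) {
    # assign: (i, d, j) array
    tot <- 0
    for (i in seq_len(nI)) {
      s <- sum(assign[i, , ])
      tot <- tot + sum(p[i, ] * apply(assign[i, , , drop = FALSE], 2, sum)) +
        q[i] * (1 - s)
    }
    tot
  }
  if (kind == "nominal") return(pen_of(bundle$x))
  if (kind == "emergency") {
    dmx <- dim(bundle$xbar)
    tot <- 0
    for (h in seq_len(dmx[1])) for (g in seq_len(dmx[2])) for (l in seq_len(dmx[3])) {
      arr <- bundle$xbar[h, g, l, , , , drop = FALSE]; dim(arr) <- dmx[4:6]
      tot <- tot + pen_of(arr)
    }
    return(tot / prod(dmx[1:3]))
  }
  dmh <- dim(bundle$xhat)
  norm <- if (is.null(noshow_norm)) nD / nI else noshow_norm
  tot <- 0
  for (b in seq_len(dmh[1])) for (g in seq_len(dmh[2])) {
    arr <- bundle$xhat[b, g, , , , drop = FALSE]; dim(arr) <- dmh[3:5]
    tot <- tot + pen_of(arr)
  }
  norm * tot
}

#' Apply an emergency scenario to the bundle
#'
#' @param bundle a \code{schedule_bundle}.
#' @param h 0-based moment; \code{g} protected day; \code{l} length class.
#' @return list: chosen OR, displaced patient ids, dropped ids, the applied
#'   restoration assignments, and the day-g elective load bound.
#' @export
apply_emergency <- function(bundle, h, g = 1L, l = 1L) {
  inst <- bundle$instance
  H <- emergency_moments(inst)
  hh <- match(h, H)
  if (is.na(hh) || g > inst$rs_days || l > length(inst$emergency_classes))
    stop("scenario (", h, ",", g, ",", l, ") is not in the bundle's plan set")
  dmx <- dim(bundle$xbar)
  arr <- bundle$xbar[hh, g, l, , , , drop = FALSE]; dim(arr) <- dmx[4:6]
  et <- which(bundle$eta[hh, g, ] == 1)
  gam <- inst$emergency_classes[l]
  list(or = et,
       displaced = inst$patients$id[bundle$chi[hh, g, ] == 1],
       dropped = inst$patients$id[bundle$mu[hh, g, l, ] == 1],
       assignments = .plan_df(arr, inst$patients$id),
       elective_load = sum(inst$patients$duration_slots * arr[, g, et]),
       load_bound = inst$capacity[g, et] - min(gam, inst$capacity[g, et] - h) +
         inst$overtime_slots)
}

#' Apply a no-show scenario to the bundle
#'
#' @param bundle a \code{schedule_bundle}.
#' @param b patient id (character) or index of the no-show.
#' @param g protected day.
#' @return list: the activated substitute, the no-show's return day, the
#'   applied assignments, and the day-g load with its bound.
#' @export
apply_noshow <- function(bundle, b, g = 1L) {
  inst <- bundle$instance
  ids <- inst$patients$id
  bi <- if (is.character(b)) match(b, ids) else as.integer(b)
  if (is.na(bi)) stop("unknown patient ", b)
  if (sum(bundle$x[bi, g, ]) < 0.5)
    stop("patient ", ids[bi], " is not nominally scheduled on day ", g)
  jb <- which(bundle$x[bi, g, ] == 1)
  dmh <- dim(bundle$xhat)
  arr <- bundle$xhat[bi, g, , , , drop = FALSE]; dim(arr) <- dmh[3:5]
  sub <- which(bundle$theta[, g, jb] == 1)
  ret <- which(apply(arr[bi, , , drop = FALSE], 2, sum) == 1)
  list(substitute = ids[sub], or = jb,
       return_day = if (length(ret)) as.integer(ret) else NA_integer_,
       assignments = .plan_df(arr, ids),
       day_load = vapply(seq_len(inst$num_ors), function(j)
         sum(inst$patients$duration_slots * arr[, g, j]), numeric(1)),
       load_bound = inst$capacity[g, ] + inst$overtime_slots)
}

#' Render a schedule as a text Gantt chart
#'
#' One row per OR, one character cell per 15-minute slot.  For restoration
#' views the row extends by the overtime allowance.
#'
#' @param bundle a \code{schedule_bundle}.
#' @param assignments optional data.frame(patient, day, or) to render
#'   instead of the nominal schedule (restoration plans have no stored
#'   ordering: patients are packed in nominal-order).
#' @param day which day to render.
#' @return character vector of lines, invisibly; printed to the console.
#' @export
render_gantt <- function(bundle, assignments = NULL, day = 1L) {
  inst <- bundle$instance
  t <- inst$patients$duration_slots
  ids <- inst$patients$id
  lines <- character(0)
  width <- inst$capacity[day, ] +
    (if (!is.null(assignments)) inst$overtime_slots else 0L)
  for (j in seq_len(inst$num_ors)) {
    cells <- rep(".", width[j])
    if (is.null(assignments) && day <= inst$rs_days) {
      dec <- decode_schedule(bundle)[[day]][[j]]
      seqp <- dec$patients; starts <- dec$start
    } else {
      sel <- if (is.null(assignments)) which(bundle$x[, day, j] == 1)
      else match(assignments$patient[assignments$day == day & assignments$or == j], ids)
      seqp <- sel[order(match(sel, seq_along(ids)))]
      starts <- if (length(seqp)) cumsum(c(1L, t[seqp][-length(seqp)])) else integer(0)
    }
    for (k in seq_along(seqp)) {
      lab <- substr(ids[seqp[k]], nchar(ids[seqp[k]]), nchar(ids[seqp[k]]))
      span <- starts[k]:(starts[k] + t[seqp[k]] - 1L)
      span <- span[span <= length(cells)]
      cells[span] <- lab
      if (starts[k] <= length(cells)) cells[starts[k]] <- "["
    }
    lines <- c(lines, sprintf("OR%d |%s|", j, paste(cells, collapse = "")))
  }
  lines <- c(lines, paste0("     ", paste(rep("-", max(width)), collapse = "")),
             sprintf("     slots 1..%d (%d min each)", max(width), inst$slot_minutes))
  cat(lines, sep = "\n")
  invisible(lines)
}
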