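# MILP construction for the disruption/restoration scheduling model.
#
# The model is assembled as sparse triplets against an abstract backend
# contract (see solver.R).  Index conventions, used everywhere:
#   i, r, b : patients, 1..nI         d, k : days, 1..nD (1-based)
#   j       : ORs, 1..nJ              g    : protected days, 1..nW (W prefix)
#   s, n    : within-day positions, 1..nS
#   h       : emergency moments, 0-based slots 0..nH-1 (stored at index h+1)
#   l       : emergency length class, 1..nL
# Surgery start slots (xi) are 1-based; emergency moments are 0-based.

#' Create an empty model handle
#'
#' @param instance an \code{or_instance}.
#' @param penalties a \code{\link{penalty_table}}; built from the instance
#'   when omitted.
#' @return a \code{milp_model} environment with variable and constraint
#'   registries.
#' @export
new_model <- function(instance, penalties = NULL) {
  if (is.null(penalties)) penalties <- penalty_table(instance)
  m <- new.env(parent = emptyenv())
  m$instance <- instance
  m$pen <- penalties
  m$nvar <- 0L
  m$vars <- list()          # name -> list(offset, dim)
  m$obj <- numeric(0)
  m$obj_const <- 0
  m$objective_id <- NA_character_
  m$lb <- numeric(0); m$ub <- numeric(0); m$vtype <- character(0)
  m$ncon <- 0L
  m$ci <- list(); m$cj <- list(); m$cx <- list()
  m$rlo <- list(); m$rhi <- list()
  m$families <- list()      # constraint registry: eq id -> rows / "bounds"
  m$family_rows <- list()   # eq id -> matrix of (start row, row count)
  m$blocks <- character(0)  # attached auxiliary blocks
  class(m) <- c("milp_model", "environment")
  m
}

.add_var_family <- function(m, name, dim, vtype = "B", lb = 0, ub = 1) {
  if (!is.null(m$vars[[name]])) stop("variable family already present: ", name)
  n <- prod(dim)
  m$vars[[name]] <- list(offset = m$nvar, dim = as.integer(dim))
  m$nvar <- m$nvar + as.integer(n)
  m$obj <- c(m$obj, numeric(n))
  m$lb <- c(m$lb, rep_len(lb, n))
  m$ub <- c(m$ub, rep_len(ub, n))
  m$vtype <- c(m$vtype, rep_len(vtype, n))
  invisible(m)
}

#' Variable ids of a family (vectorized over index components)
#'
#' Index components are recycled to a common length; 0-based moment
#' indices \code{h} must be passed as \code{h + 1}.
#' @param m model handle.
#' @param name family name.
#' @param ... one integer vector per dimension.
#' @return integer vector of global variable ids.
#' @export
vid <- function(m, name, ...) {
  fam <- m$vars[[name]]
  if (is.null(fam)) stop("unknown variable family: ", name)
  idx <- list(...)
  if (length(idx) != length(fam$dim))
    stop(name, " expects ", length(fam$dim), " indices")
  n <- max(lengths(idx))
  out <- rep_len(as.integer(idx[[1L]]), n)
  stride <- 1L
  for (k in seq_along(idx)[-1L]) {
    stride <- stride * fam$dim[k - 1L]
    out <- out + (rep_len(as.integer(idx[[k]]), n) - 1L) * stride
  }
  fam$offset + out
}

.fam_values <- function(m, name, x) {
  fam <- m$vars[[name]]
  if (is.null(fam)) stop("unknown variable family: ", name)
  array(x[fam$offset + seq_len(prod(fam$dim))], dim = fam$dim)
}

# Append a batch of constraint rows.  row: local 1..k row ids (may repeat,
# one entry per nonzero); col: variable ids; sense in {"<=", ">=", "="}.
.add_cons <- function(m, eq, row, col, coef, sense, rhs) {
  nr <- length(rhs)
  if (nr == 0L) {
    m$families[[eq]] <- (m$families[[eq]] %||% 0L)
    return(invisible(m))
  }
  keep <- coef != 0
  m$ci[[length(m$ci) + 1L]] <- m$ncon + as.integer(row)[keep]
  m$cj[[length(m$cj) + 1L]] <- as.integer(col)[keep]
  m$cx[[length(m$cx) + 1L]] <- as.numeric(coef)[keep]
  sense <- rep_len(sense, nr)
  lo <- ifelse(sense == "<=", -Inf, rhs)
  hi <- ifelse(sense == ">=", Inf, rhs)
  m$rlo[[length(m$rlo) + 1L]] <- as.numeric(lo)
  m$rhi[[length(m$rhi) + 1L]] <- as.numeric(hi)
  m$families[[eq]] <- (m$families[[eq]] %||% 0L) + nr
  m$family_rows[[eq]] <- rbind(m$family_rows[[eq]],
                               c(start = m$ncon + 1L, n = nr))
  m$ncon <- m$ncon + nr
  invisible(m)
}

#' Inspect one constraint row
#'
#' @param m a \code{milp_model}.
#' @param eq constraint family id (e.g. \code{"eq36"}).
#' @param k local row index within the family.
#' @return list: variable ids, coefficients, row bounds.
#' @export
constraint_row <- function(m, eq, k = 1L) {
  fr <- m$family_rows[[eq]]
  if (is.null(fr)) stop("no rows recorded for family ", eq)
  rows <- unlist(lapply(seq_len(nrow(fr)), function(r)
    seq(fr[r, 1], length.out = fr[r, 2])))
  target <- rows[k]
  ai <- unlist(m$ci, use.names = FALSE)
  aj <- unlist(m$cj, use.names = FALSE)
  ax <- unlist(m$cx, use.names = FALSE)
  sel <- ai == target
  rlo <- unlist(m$rlo, use.names = FALSE)
  rhi <- unlist(m$rhi, use.names = FALSE)
  list(vars = aj[sel], coefs = ax[sel], lo = rlo[target], hi = rhi[target])
}

.mark_bounds_family <- function(m, eq) {
  m$families[[eq]] <- "bounds"
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.dims <- function(m) {
  inst <- m$instance
  list(nI = nrow(inst$patients), nD = inst$horizon_days, nJ = inst$num_ors,
       nW = inst$rs_days, nH = length(emergency_moments(inst)),
       nL = length(inst$emergency_classes),
       nS = max_positions(inst), t = inst$patients$duration_slots,
       Tc = inst$capacity, M = m$instance$big_m, eps = inst$epsilon)
}

.eg <- function(...) expand.grid(..., KEEP.OUT.ATTRS = FALSE)

# ---- Block A ---------------------------------------------------------------

.block_A <- function(m) {
  dm <- .dims(m); inst <- m$instance
  with(dm, {
    # (4): each patient scheduled at most once
    g4 <- .eg(i = 1:nI, d = 1:nD, j = 1:nJ)
    .add_cons(m, "eq4", row = g4$i, col = vid(m, "x", g4$i, g4$d, g4$j),
              coef = rep(1, nrow(g4)), sense = "<=", rhs = rep(1, nI))
    # (5): compatibility, realized as variable upper bounds (the x family's
    # linear layout (i, d, j) matches the compatibility array's)
    fx <- m$vars[["x"]]
    m$ub[fx$offset + seq_len(prod(fx$dim))] <-
      pmin(m$ub[fx$offset + seq_len(prod(fx$dim))],
           as.vector(inst$compatibility))
    .mark_bounds_family(m, "eq5")
    # (6): OR-day capacity
    g6 <- .eg(i = 1:nI, d = 1:nD, j = 1:nJ)
    rowid <- g6$d + (g6$j - 1L) * nD
    .add_cons(m, "eq6", row = rowid, col = vid(m, "x", g6$i, g6$d, g6$j),
              coef = t[g6$i], sense = "<=", rhs = as.vector(Tc))
  })
  invisible(m)
}

# ---- Block B: ordering on protected days ----------------------------------

.block_B <- function(m) {
  dm <- .dims(m); inst <- m$instance
  with(dm, {
    # (8): sum_s y = x on protected days
    g8 <- .eg(i = 1:nI, g = 1:nW, j = 1:nJ)
    nr8 <- nrow(g8)
    row <- integer(0); col <- integer(0); coef <- numeric(0)
    for (s in 1:nS) {
      row <- c(row, seq_len(nr8))
      col <- c(col, vid(m, "y", g8$i, g8$g, g8$j, rep(s, nr8)))
      coef <- c(coef, rep(1, nr8))
    }
    row <- c(row, seq_len(nr8))
    col <- c(col, vid(m, "x", g8$i, g8$g, g8$j))
    coef <- c(coef, rep(-1, nr8))
    .add_cons(m, "eq8", row, col, coef, "=", rep(0, nr8))

    # (9): positions filled in order
    if (nS > 1L) {
      g9 <- .eg(i = 1:nI, j = 1:nJ, g = 1:nW, s = 1:(nS - 1L))
      rowid <- g9$j + (g9$g - 1L) * nJ + (g9$s - 1L) * nJ * nW
      nr9 <- nJ * nW * (nS - 1L)
      .add_cons(m, "eq9",
                row = c(rowid, rowid),
                col = c(vid(m, "y", g9$i, g9$g, g9$j, g9$s + 1L),
                        vid(m, "y", g9$i, g9$g, g9$j, g9$s)),
                coef = c(rep(1, nrow(g9)), rep(-1, nrow(g9))),
                sense = "<=", rhs = rep(0, nr9))
    } else .add_cons(m, "eq9", integer(0), integer(0), numeric(0), "<=", numeric(0))

    # (10): each position used at most once
    g10 <- .eg(i = 1:nI, j = 1:nJ, g = 1:nW, s = 1:nS)
    rowid <- g10$j + (g10$g - 1L) * nJ + (g10$s - 1L) * nJ * nW
    .add_cons(m, "eq10", row = rowid,
              col = vid(m, "y", g10$i, g10$g, g10$j, g10$s),
              coef = rep(1, nrow(g10)), sense = "<=",
              rhs = rep(1, nJ * nW * nS))

    # (11): start slot = predecessors' durations + 1 (nu[i,r,.]: r precedes i)
    g11 <- .eg(i = 1:nI, g = 1:nW, j = 1:nJ)
    nr11 <- nrow(g11)
    row <- c(seq_len(nr11), seq_len(nr11))
    col <- c(vid(m, "xi", g11$i, g11$g, g11$j), vid(m, "x", g11$i, g11$g, g11$j))
    coef <- c(rep(1, nr11), rep(-1, nr11))
    for (r in 1:nI) {
      sel <- which(g11$i != r)
      row <- c(row, sel)
      col <- c(col, vid(m, "nu", g11$i[sel], rep(r, length(sel)),
                        g11$g[sel], g11$j[sel]))
      coef <- c(coef, rep(-t[r], length(sel)))
    }
    .add_cons(m, "eq11", row, col, coef, "=", rep(0, nr11))

    # (12): position order implies precedence
    g12 <- .eg(i = 1:nI, r = 1:nI, g = 1:nW, j = 1:nJ, s = 1:nS)
    g12 <- g12[g12$i != g12$r, , drop = FALSE]
    nr12 <- nrow(g12)
    rowid <- seq_len(nr12)
    row <- c(rowid, rowid)
    col <- c(vid(m, "y", g12$i, g12$g, g12$j, g12$s),
             vid(m, "nu", g12$i, g12$r, g12$g, g12$j))
    coef <- c(rep(1, nr12), rep(-1, nr12))
    for (n in 1:(max(nS - 1L, 1L))) {
      sel <- which(g12$s > n)
      if (length(sel)) {
        row <- c(row, rowid[sel])
        col <- c(col, vid(m, "y", g12$r[sel], g12$g[sel], g12$j[sel],
                          rep(n, length(sel))))
        coef <- c(coef, rep(1, length(sel)))
      }
    }
    .add_cons(m, "eq12", row, col, coef, "<=", rep(1, nr12))

    # (13): precedence only w.r.t. scheduled patients
    g13 <- .eg(i = 1:nI, r = 1:nI, g = 1:nW, j = 1:nJ)
    g13 <- g13[g13$i != g13$r, , drop = FALSE]
    nr13 <- nrow(g13)
    .add_cons(m, "eq13", row = c(seq_len(nr13), seq_len(nr13)),
              col = c(vid(m, "nu", g13$i, g13$r, g13$g, g13$j),
                      vid(m, "x", g13$r, g13$g, g13$j)),
              coef = c(rep(1, nr13), rep(-1, nr13)),
              sense = "<=", rhs = rep(0, nr13))

    # (14): antisymmetry
    g14 <- .eg(i = 1:nI, r = 1:nI, g = 1:nW, j = 1:nJ)
    g14 <- g14[g14$i < g14$r, , drop = FALSE]
    nr14 <- nrow(g14)
    .add_cons(m, "eq14", row = c(seq_len(nr14), seq_len(nr14)),
              col = c(vid(m, "nu", g14$i, g14$r, g14$g, g14$j),
                      vid(m, "nu", g14$r, g14$i, g14$g, g14$j)),
              coef = rep(1, 2L * nr14), sense = "<=", rhs = rep(1, nr14))

    # (15): start slot zero when unscheduled, and fits within the day
    g15 <- .eg(i = 1:nI, g = 1:nW, j = 1:nJ)
    nr15 <- nrow(g15)
    Tgj <- Tc[cbind(g15$g, g15$j)]
    .add_cons(m, "eq15", row = c(seq_len(nr15), seq_len(nr15)),
              col = c(vid(m, "xi", g15$i, g15$g, g15$j),
                      vid(m, "x", g15$i, g15$g, g15$j)),
              coef = c(rep(1, nr15), -(Tgj + 1 - t[g15$i])),
              sense = "<=", rhs = rep(0, nr15))
  })
  invisible(m)
}

# ---- Block C: OR state at each moment -------------------------------------

.block_C <- function(m) {
  dm <- .dims(m)
  with(dm, {
    g16 <- .eg(i = 1:nI, g = 1:nW, j = 1:nJ)
    nr <- nrow(g16)
    .add_cons(m, "eq16", row = rep(seq_len(nr), 3L),
              col = c(vid(m, "C", g16$g, g16$j),
                      vid(m, "xi", g16$i, g16$g, g16$j),
                      vid(m, "x", g16$i, g16$g, g16$j)),
              coef = c(rep(1, nr), rep(-1, nr), -t[g16$i]),
              sense = ">=", rhs = rep(0, nr))

    gh <- .eg(h = 1:nH, g = 1:nW, j = 1:nJ)   # h column holds h+1
    nrh <- nrow(gh)
    # (17):  h - C <= M rho
    .add_cons(m, "eq17", row = rep(seq_len(nrh), 2L),
              col = c(vid(m, "C", gh$g, gh$j), vid(m, "rho", gh$h, gh$g, gh$j)),
              coef = c(rep(-1, nrh), rep(-M, nrh)),
              sense = "<=", rhs = -(gh$h - 1))
    # (18):  h - C >= rho - M(1-rho) - 1  <=>  C + (1+M) rho <= M + 1 + h
    .add_cons(m, "eq18", row = rep(seq_len(nrh), 2L),
              col = c(vid(m, "C", gh$g, gh$j), vid(m, "rho", gh$h, gh$g, gh$j)),
              coef = c(rep(1, nrh), rep(1 + M, nrh)),
              sense = "<=", rhs = M + 1 + (gh$h - 1))
    # (19): exactly one operating patient unless the OR is empty
    g19 <- .eg(i = 1:nI, g = 1:nW, j = 1:nJ, h = 1:nH)
    rowid <- gh$h + (gh$g - 1L) * nH + (gh$j - 1L) * nH * nW
    rowid19 <- g19$h + (g19$g - 1L) * nH + (g19$j - 1L) * nH * nW
    .add_cons(m, "eq19",
              row = c(rowid19, rowid),
              col = c(vid(m, "lam", g19$i, g19$g, g19$j, g19$h),
                      vid(m, "rho", gh$h, gh$g, gh$j)),
              coef = c(rep(1, nrow(g19)), rep(1, nrh)),
              sense = "=", rhs = rep(1, nrh))

    gi <- .eg(i = 1:nI, g = 1:nW, j = 1:nJ, h = 2:nH)  # h != 0
    nri <- nrow(gi)
    # (20): operating patient's end >= h
    .add_cons(m, "eq20", row = rep(seq_len(nri), 3L),
              col = c(vid(m, "xi", gi$i, gi$g, gi$j),
                      vid(m, "x", gi$i, gi$g, gi$j),
                      vid(m, "lam", gi$i, gi$g, gi$j, gi$h)),
              coef = c(rep(1, nri), t[gi$i], -(gi$h - 1)),
              sense = ">=", rhs = rep(0, nri))
    # (21): operating patient's start <= h
    .add_cons(m, "eq21", row = rep(seq_len(nri), 2L),
              col = c(vid(m, "xi", gi$i, gi$g, gi$j),
                      vid(m, "lam", gi$i, gi$g, gi$j, gi$h)),
              coef = c(rep(1, nri), M - (gi$h - 1)),
              sense = "<=", rhs = rep(M, nri))
    # (22)/(23): first availability equals the operating patient's end
    ga <- .eg(i = 1:nI, g = 1:nW, j = 1:nJ, h = 1:nH)
    nra <- nrow(ga)
    .add_cons(m, "eq22", row = rep(seq_len(nra), 4L),
              col = c(vid(m, "Xi", ga$h, ga$g, ga$j),
                      vid(m, "xi", ga$i, ga$g, ga$j),
                      vid(m, "x", ga$i, ga$g, ga$j),
                      vid(m, "lam", ga$i, ga$g, ga$j, ga$h)),
              coef = c(rep(1, nra), rep(-1, nra), -t[ga$i], rep(-M, nra)),
              sense = ">=", rhs = rep(-M, nra))
    .add_cons(m, "eq23", row = rep(seq_len(nra), 4L),
              col = c(vid(m, "Xi", ga$h, ga$g, ga$j),
                      vid(m, "xi", ga$i, ga$g, ga$j),
                      vid(m, "x", ga$i, ga$g, ga$j),
                      vid(m, "lam", ga$i, ga$g, ga$j, ga$h)),
              coef = c(rep(1, nra), rep(-1, nra), -t[ga$i], rep(M, nra)),
              sense = "<=", rhs = rep(M, nra))
    # Tightening: when the OR is already empty at h, its first availability
    # is h itself.  Without this the availability of an empty OR is a free
    # variable, which would let an emergency be routed to a busy OR while an
    # idle one exists -- contradicting the first-available-OR rule that the
    # availability machinery is meant to enforce.
    .add_cons(m, "eqXiEmptyLo", row = rep(seq_len(nrh), 2L),
              col = c(vid(m, "Xi", gh$h, gh$g, gh$j),
                      vid(m, "rho", gh$h, gh$g, gh$j)),
              coef = c(rep(1, nrh), -(gh$h - 1)),
              sense = ">=", rhs = rep(0, nrh))
    .add_cons(m, "eqXiEmptyHi", row = rep(seq_len(nrh), 2L),
              col = c(vid(m, "Xi", gh$h, gh$g, gh$j),
                      vid(m, "rho", gh$h, gh$g, gh$j)),
              coef = c(rep(1, nrh), M - (gh$h - 1)),
              sense = "<=", rhs = rep(M, nrh))
  })
  invisible(m)
}

# ---- Block D: emergency-to-OR assignment ----------------------------------

.block_D <- function(m) {
  dm <- .dims(m)
  with(dm, {
    g24 <- .eg(h = 1:nH, g = 1:nW, j = 1:nJ)
    rowid <- g24$h + (g24$g - 1L) * nH
    .add_cons(m, "eq24", row = rowid,
              col = vid(m, "eta", g24$h, g24$g, g24$j),
              coef = rep(1, nrow(g24)), sense = "=", rhs = rep(1, nH * nW))
    # (25): assigned OR is first available
    g25 <- .eg(g = 1:nW, j = 1:nJ, k = 1:nJ, h = 1:nH)
    g25 <- g25[g25$j != g25$k, , drop = FALSE]
    nr <- nrow(g25)
    .add_cons(m, "eq25", row = rep(seq_len(nr), 3L),
              col = c(vid(m, "Xi", g25$h, g25$g, g25$j),
                      vid(m, "Xi", g25$h, g25$g, g25$k),
                      vid(m, "eta", g25$h, g25$g, g25$j)),
              coef = c(rep(1, nr), rep(-1, nr), rep(M, nr)),
              sense = "<=", rhs = rep(M, nr))
  })
  invisible(m)
}

# ---- Block E: emergency impact and reschedule coverage --------------------

.block_E <- function(m, eq29_window = c("printed", "rs_day")) {
  eq29_window <- match.arg(eq29_window)
  dm <- .dims(m); inst <- m$instance
  with(dm, {
    Delta <- inst$delta_max
    # (26) restates (11); implemented once there.
    m$families[["eq26"]] <- "alias:eq11"
    # (27): chi only for surgeries starting strictly after h
    g27 <- .eg(i = 1:nI, g = 1:nW, h = 1:nH)
    nr27 <- nrow(g27)
    row <- rep(seq_len(nr27), nJ + 1L)
    col <- vid(m, "chi", g27$h, g27$g, g27$i)
    coef <- -((g27$h - 1) + eps)
    for (j in 1:nJ) {
      col <- c(col, vid(m, "xi", g27$i, g27$g, rep(j, nr27)))
      coef <- c(coef, rep(1, nr27))
    }
    .add_cons(m, "eq27", row, col, coef, ">=", rep(0, nr27))

    # (28): impacted patients must appear in the reschedule within the window
    g28 <- .eg(i = 1:nI, h = 1:nH, g = 1:nW, l = 1:nL)
    nr28 <- nrow(g28)
    row <- seq_len(nr28)
    col <- vid(m, "chi", g28$h, g28$g, g28$i)
    coef <- rep(-1, nr28)
    for (d in 1:nD) for (j in 1:nJ) {
      sel <- which(d < g28$g + Delta)
      if (length(sel)) {
        row <- c(row, sel)
        col <- c(col, vid(m, "xbar", g28$h[sel], g28$g[sel], g28$l[sel],
                          g28$i[sel], rep(d, length(sel)), rep(j, length(sel))))
        coef <- c(coef, rep(1, length(sel)))
      }
    }
    .add_cons(m, "eq28", row, col, coef, ">=", rep(0, nr28))

    # (29): every nominal assignment is recovered within Delta days, or the
    # patient is flagged as dropped (mu)
    g29 <- .eg(h = 1:nH, g = 1:nW, l = 1:nL, i = 1:nI, d = 1:nD)
    nr29 <- nrow(g29)
    row <- seq_len(nr29)
    col <- vid(m, "mu", g29$h, g29$g, g29$l, g29$i)
    coef <- rep(1, nr29)
    for (j in 1:nJ) {
      row <- c(row, seq_len(nr29))
      col <- c(col, vid(m, "x", g29$i, g29$d, rep(j, nr29)))
      coef <- c(coef, rep(-1, nr29))
    }
    for (off in 0:Delta) for (j in 1:nJ) {
      if (eq29_window == "printed") {
        sel <- which(g29$d + off <= nD)
        kk <- g29$d[sel] + off
      } else {                       # window anchored at the disrupted day g
        sel <- which(g29$g + off <= nD & g29$g + off >= g29$d)
        kk <- g29$g[sel] + off
      }
      if (length(sel)) {
        row <- c(row, sel)
        col <- c(col, vid(m, "xbar", g29$h[sel], g29$g[sel], g29$l[sel],
                          g29$i[sel], kk, rep(j, length(sel))))
        coef <- c(coef, rep(1, length(sel)))
      }
    }
    .add_cons(m, "eq29", row, col, coef, ">=", rep(0, nr29))
  })
  invisible(m)
}

# ---- Block F: emergency reschedules ---------------------------------------

.block_F <- function(m) {
  dm <- .dims(m); inst <- m$instance
  with(dm, {
    Om <- inst$overtime_slots
    # (30): no anticipation w.r.t. the nominal day (d = 1 rows are implied
    # by (4) and carry an empty inner sum; omitted)
    g30 <- .eg(i = 1:nI, d = 2:nD, h = 1:nH, g = 1:nW, l = 1:nL)
    nr30 <- nrow(g30)
    row <- integer(0); col <- integer(0); coef <- numeric(0)
    for (j in 1:nJ) {
      row <- c(row, seq_len(nr30))
      col <- c(col, vid(m, "x", g30$i, g30$d, rep(j, nr30)))
      coef <- c(coef, rep(1, nr30))
      for (k in 1:(nD - 1L)) {
        sel <- which(g30$d > k)
        if (length(sel)) {
          row <- c(row, sel)
          col <- c(col, vid(m, "xbar", g30$h[sel], g30$g[sel], g30$l[sel],
                            g30$i[sel], rep(k, length(sel)),
                            rep(j, length(sel))))
          coef <- c(coef, rep(1, length(sel)))
        }
      }
    }
    .add_cons(m, "eq30", row, col, coef, "<=", rep(1, nr30))

    # (31): only nominally scheduled patients appear in the reschedule
    g31 <- .eg(h = 1:nH, g = 1:nW, l = 1:nL, i = 1:nI)
    nr31 <- nrow(g31)
    row <- integer(0); col <- integer(0); coef <- numeric(0)
    for (d in 1:nD) for (j in 1:nJ) {
      row <- c(row, seq_len(nr31), seq_len(nr31))
      col <- c(col, vid(m, "xbar", g31$h, g31$g, g31$l, g31$i,
                        rep(d, nr31), rep(j, nr31)),
               vid(m, "x", g31$i, rep(d, nr31), rep(j, nr31)))
      coef <- c(coef, rep(1, nr31), rep(-1, nr31))
    }
    .add_cons(m, "eq31", row, col, coef, "<=", rep(0, nr31))

    # (32): unimpacted day-g patients keep their assignment
    g32 <- .eg(h = 1:nH, g = 1:nW, i = 1:nI, j = 1:nJ, l = 1:nL)
    nr32 <- nrow(g32)
    .add_cons(m, "eq32", row = rep(seq_len(nr32), 3L),
              col = c(vid(m, "xbar", g32$h, g32$g, g32$l, g32$i, g32$g, g32$j),
                      vid(m, "x", g32$i, g32$g, g32$j),
                      vid(m, "chi", g32$h, g32$g, g32$i)),
              coef = c(rep(1, nr32), rep(-1, nr32), rep(1, nr32)),
              sense = ">=", rhs = rep(0, nr32))

    # (33): at most one assignment per patient per scenario
    g33 <- .eg(h = 1:nH, g = 1:nW, l = 1:nL, i = 1:nI)
    nr33 <- nrow(g33)
    row <- integer(0); col <- integer(0)
    for (d in 1:nD) for (j in 1:nJ) {
      row <- c(row, seq_len(nr33))
      col <- c(col, vid(m, "xbar", g33$h, g33$g, g33$l, g33$i,
                        rep(d, nr33), rep(j, nr33)))
    }
    .add_cons(m, "eq33", row, col, rep(1, length(col)), "<=", rep(1, nr33))

    # (34): compatibility, realized as upper bounds
    av <- as.vector(inst$compatibility)            # (i,d,j) order
    fam <- m$vars[["xbar"]]
    m$ub[fam$offset + seq_len(prod(fam$dim))] <-
      pmin(m$ub[fam$offset + seq_len(prod(fam$dim))],
           rep(av, each = nH * nW * nL))
    .mark_bounds_family(m, "eq34")

    # (35): capacity on days after the disruption
    g35 <- .eg(i = 1:nI, h = 1:nH, g = 1:nW, l = 1:nL, j = 1:nJ, d = 1:nD)
    g35 <- g35[g35$d > g35$g, , drop = FALSE]
    key <- .eg(h = 1:nH, g = 1:nW, l = 1:nL, j = 1:nJ, d = 1:nD)
    key <- key[key$d > key$g, , drop = FALSE]
    rid <- match(paste(g35$h, g35$g, g35$l, g35$j, g35$d),
                 paste(key$h, key$g, key$l, key$j, key$d))
    .add_cons(m, "eq35", row = rid,
              col = vid(m, "xbar", g35$h, g35$g, g35$l, g35$i, g35$d, g35$j),
              coef = t[g35$i], sense = "<=",
              rhs = Tc[cbind(key$d, key$j)])

    # (36): day-g capacity net of the emergency, plus overtime
    g36 <- .eg(i = 1:nI, j = 1:nJ, h = 1:nH, g = 1:nW, l = 1:nL)
    key <- .eg(j = 1:nJ, h = 1:nH, g = 1:nW, l = 1:nL)
    rid <- match(paste(g36$j, g36$h, g36$g, g36$l),
                 paste(key$j, key$h, key$g, key$l))
    Tgj <- Tc[cbind(key$g, key$j)]
    gam <- inst$emergency_classes[key$l]
    cut <- pmin(gam, Tgj - (key$h - 1))
    row <- c(rid, seq_len(nrow(key)))
    col <- c(vid(m, "xbar", g36$h, g36$g, g36$l, g36$i, g36$g, g36$j),
             vid(m, "eta", key$h, key$g, key$j))
    coef <- c(t[g36$i], cut)
    .add_cons(m, "eq36", row, col, coef, "<=", Tgj + Om)
  })
  invisible(m)
}

# ---- Blocks G & H: no-show substitutes and reschedules --------------------

.block_GH <- function(m, noshow_mode = c("fixed_delay", "window")) {
  noshow_mode <- match.arg(noshow_mode)
  dm <- .dims(m); inst <- m$instance
  with(dm, {
    Om <- inst$overtime_slots
    Dh <- inst$delta_noshow
    Delta <- inst$delta_max
    nB <- nI                                   # scenario index b over patients

    # (37): exactly one designated substitute per (OR, protected day)
    g37 <- .eg(i = 1:nI, j = 1:nJ, g = 1:nW)
    rowid <- g37$j + (g37$g - 1L) * nJ
    .add_cons(m, "eq37", row = rowid,
              col = vid(m, "theta", g37$i, g37$g, g37$j),
              coef = rep(1, nrow(g37)), sense = "=", rhs = rep(1, nJ * nW))

    # (38): the substitute is nominally scheduled on day g+1
    g38 <- .eg(i = 1:nI, g = 1:nW)
    nr38 <- nrow(g38)
    row <- integer(0); col <- integer(0); coef <- numeric(0)
    for (j in 1:nJ) {
      row <- c(row, seq_len(nr38), seq_len(nr38))
      col <- c(col, vid(m, "theta", g38$i, g38$g, rep(j, nr38)),
               vid(m, "x", g38$i, g38$g + 1L, rep(j, nr38)))
      coef <- c(coef, rep(1, nr38), rep(-1, nr38))
    }
    .add_cons(m, "eq38", row, col, coef, "<=", rep(0, nr38))

    # (39): substitute compatibility with (g, j), as bounds
    fam <- m$vars[["theta"]]
    aw <- inst$compatibility[, seq_len(nW), , drop = FALSE]
    m$ub[fam$offset + seq_len(prod(fam$dim))] <-
      pmin(m$ub[fam$offset + seq_len(prod(fam$dim))], as.vector(aw))
    .mark_bounds_family(m, "eq39")

    # (40): the substitute covers the no-show's (g, j) slot
    g40 <- .eg(b = 1:nB, g = 1:nW, i = 1:nI, j = 1:nJ)
    nr40 <- nrow(g40)
    .add_cons(m, "eq40", row = rep(seq_len(nr40), 3L),
              col = c(vid(m, "xhat", g40$b, g40$g, g40$i, g40$g, g40$j),
                      vid(m, "theta", g40$i, g40$g, g40$j),
                      vid(m, "x", g40$b, g40$g, g40$j)),
              coef = c(rep(1, nr40), rep(-1, nr40), rep(-1, nr40)),
              sense = ">=", rhs = rep(-1, nr40))

    if (noshow_mode == "fixed_delay") {
      # (41): the no-show returns exactly Dh days later
      g41 <- .eg(b = 1:nB, g = 1:nW)
      nr41 <- nrow(g41)
      row <- integer(0); col <- integer(0); coef <- numeric(0)
      for (j in 1:nJ) {
        row <- c(row, seq_len(nr41), seq_len(nr41))
        col <- c(col, vid(m, "xhat", g41$b, g41$g, g41$b, g41$g + Dh, rep(j, nr41)),
                 vid(m, "x", g41$b, g41$g, rep(j, nr41)))
        coef <- c(coef, rep(1, nr41), rep(-1, nr41))
      }
      .add_cons(m, "eq41", row, col, coef, ">=", rep(0, nr41))
    } else {
      # (42): the no-show returns within Delta days
      g42 <- .eg(b = 1:nB, g = 1:nW)
      nr42 <- nrow(g42)
      row <- integer(0); col <- integer(0); coef <- numeric(0)
      for (j in 1:nJ) {
        row <- c(row, seq_len(nr42))
        col <- c(col, vid(m, "x", g42$b, g42$g, rep(j, nr42)))
        coef <- c(coef, rep(-1, nr42))
        for (d in 1:nD) {
          sel <- which(d < g42$g + Delta)
          if (length(sel)) {
            row <- c(row, sel)
            col <- c(col, vid(m, "xhat", g42$b[sel], g42$g[sel], g42$b[sel],
                              rep(d, length(sel)), rep(j, length(sel))))
            coef <- c(coef, rep(1, length(sel)))
          }
        }
      }
      .add_cons(m, "eq42", row, col, coef, ">=", rep(0, nr42))
    }

    # (43): at most one assignment per patient per no-show scenario
    g43 <- .eg(b = 1:nB, g = 1:nW, i = 1:nI)
    nr43 <- nrow(g43)
    row <- integer(0); col <- integer(0)
    for (d in 1:nD) for (j in 1:nJ) {
      row <- c(row, seq_len(nr43))
      col <- c(col, vid(m, "xhat", g43$b, g43$g, g43$i, rep(d, nr43), rep(j, nr43)))
    }
    .add_cons(m, "eq43", row, col, rep(1, length(col)), "<=", rep(1, nr43))

    # (44): compatibility, as bounds
    fam <- m$vars[["xhat"]]
    av <- as.vector(inst$compatibility)
    m$ub[fam$offset + seq_len(prod(fam$dim))] <-
      pmin(m$ub[fam$offset + seq_len(prod(fam$dim))], rep(av, each = nB * nW))
    .mark_bounds_family(m, "eq44")

    # (45): capacity on later days
    g45 <- .eg(i = 1:nI, b = 1:nB, g = 1:nW, j = 1:nJ, d = 1:nD)
    g45 <- g45[g45$d > g45$g, , drop = FALSE]
    key <- .eg(b = 1:nB, g = 1:nW, j = 1:nJ, d = 1:nD)
    key <- key[key$d > key$g, , drop = FALSE]
    rid <- match(paste(g45$b, g45$g, g45$j, g45$d),
                 paste(key$b, key$g, key$j, key$d))
    .add_cons(m, "eq45", row = rid,
              col = vid(m, "xhat", g45$b, g45$g, g45$i, g45$d, g45$j),
              coef = t[g45$i], sense = "<=", rhs = Tc[cbind(key$d, key$j)])

    # (46): day-g capacity with overtime for the substitute
    g46 <- .eg(i = 1:nI, b = 1:nB, g = 1:nW, j = 1:nJ)
    key <- .eg(b = 1:nB, g = 1:nW, j = 1:nJ)
    rid <- match(paste(g46$b, g46$g, g46$j), paste(key$b, key$g, key$j))
    .add_cons(m, "eq46", row = rid,
              col = vid(m, "xhat", g46$b, g46$g, g46$i, g46$g, g46$j),
              coef = t[g46$i], sense = "<=",
              rhs = Tc[cbind(key$g, key$j)] + Om)

    # (47): no anticipation -- except that the activated substitute may be
    # pulled forward to the protected day itself.  The printed constraint
    # contradicts the substitute mechanism (a substitute is, by design,
    # anticipated from day g+1 to day g); it is therefore split: strict
    # anticipation bans for days after g (47a) and an exemption for day g
    # limited to the substitute of the OR on which the no-show b actually
    # sits (activation variable z <= theta, z <= x, linearizing theta*x).
    gz <- .eg(b = 1:nB, g = 1:nW, i = 1:nI, j = 1:nJ)
    nrz <- nrow(gz)
    .add_cons(m, "eqSubActTheta", row = rep(seq_len(nrz), 2L),
              col = c(vid(m, "subact", gz$b, gz$g, gz$i, gz$j),
                      vid(m, "theta", gz$i, gz$g, gz$j)),
              coef = c(rep(1, nrz), rep(-1, nrz)), sense = "<=",
              rhs = rep(0, nrz))
    .add_cons(m, "eqSubActX", row = rep(seq_len(nrz), 2L),
              col = c(vid(m, "subact", gz$b, gz$g, gz$i, gz$j),
                      vid(m, "x", gz$b, gz$g, gz$j)),
              coef = c(rep(1, nrz), rep(-1, nrz)), sense = "<=",
              rhs = rep(0, nrz))
    g47 <- .eg(i = 1:nI, d = 2:nD, b = 1:nB, g = 1:nW)
    nr47 <- nrow(g47)
    rowa <- integer(0); cola <- integer(0); coefa <- numeric(0)
    rowb <- integer(0); colb <- integer(0); coefb <- numeric(0)
    for (j in 1:nJ) {
      rowa <- c(rowa, seq_len(nr47))
      cola <- c(cola, vid(m, "x", g47$i, g47$d, rep(j, nr47)))
      coefa <- c(coefa, rep(1, nr47))
      rowb <- c(rowb, seq_len(nr47), seq_len(nr47))
      colb <- c(colb, vid(m, "x", g47$i, g47$d, rep(j, nr47)),
                vid(m, "subact", g47$b, g47$g, g47$i, rep(j, nr47)))
      coefb <- c(coefb, rep(1, nr47), rep(-1, nr47))
      for (k in 1:(nD - 1L)) {
        sela <- which(g47$d > k & k > g47$g)
        if (length(sela)) {
          rowa <- c(rowa, sela)
          cola <- c(cola, vid(m, "xhat", g47$b[sela], g47$g[sela], g47$i[sela],
                              rep(k, length(sela)), rep(j, length(sela))))
          coefa <- c(coefa, rep(1, length(sela)))
        }
        selb <- which(g47$d > k & k <= g47$g)
        if (length(selb)) {
          rowb <- c(rowb, selb)
          colb <- c(colb, vid(m, "xhat", g47$b[selb], g47$g[selb], g47$i[selb],
                              rep(k, length(selb)), rep(j, length(selb))))
          coefb <- c(coefb, rep(1, length(selb)))
        }
      }
    }
    .add_cons(m, "eq47", rowa, cola, coefa, "<=", rep(1, nr47))
    .add_cons(m, "eq47b", rowb, colb, coefb, "<=", rep(1, nr47))

    # (48): only nominally scheduled patients appear
    g48 <- .eg(b = 1:nB, g = 1:nW, i = 1:nI)
    nr48 <- nrow(g48)
    row <- integer(0); col <- integer(0); coef <- numeric(0)
    for (d in 1:nD) for (j in 1:nJ) {
      row <- c(row, seq_len(nr48), seq_len(nr48))
      col <- c(col, vid(m, "xhat", g48$b, g48$g, g48$i, rep(d, nr48), rep(j, nr48)),
               vid(m, "x", g48$i, rep(d, nr48), rep(j, nr48)))
      coef <- c(coef, rep(1, nr48), rep(-1, nr48))
    }
    .add_cons(m, "eq48", row, col, coef, "<=", rep(0, nr48))

    # (49): day-g patients other than the no-show are retained
    g49 <- .eg(b = 1:nB, g = 1:nW, i = 1:nI, j = 1:nJ)
    g49 <- g49[g49$i != g49$b, , drop = FALSE]
    nr49 <- nrow(g49)
    .add_cons(m, "eq49", row = rep(seq_len(nr49), 2L),
              col = c(vid(m, "xhat", g49$b, g49$g, g49$i, g49$g, g49$j),
                      vid(m, "x", g49$i, g49$g, g49$j)),
              coef = c(rep(1, nr49), rep(-1, nr49)),
              sense = ">=", rhs = rep(0, nr49))
  })
  invisible(m)
}

# ---- public builders -------------------------------------------------------

#' Build the nominal assignment model (Block A, objective on penalties)
#'
#' @param instance an \code{or_instance}.
#' @param penalties optional \code{\link{penalty_table}}.
#' @return a \code{milp_model} ready to solve.
#' @export
build_nominal_model <- function(instance, penalties = NULL) {
  m <- new_model(instance, penalties)
  dm <- .dims(m)
  .add_var_family(m, "x", c(dm$nI, dm$nD, dm$nJ), "B")
  .block_A(m)
  set_objective(m, "nominal")
  m
}

#' Build the complete model: nominal schedule plus all restoration plans
#'
#' Registers every decision-variable family and all constraint blocks:
#' assignment (A), within-day ordering on protected days (B), per-moment OR
#' state (C), emergency-to-OR assignment (D), emergency impact (E),
#' emergency reschedules (F), no-show substitutes (G) and no-show
#' reschedules (H).
#'
#' @param instance an \code{or_instance}.
#' @param penalties optional penalty table.
#' @param noshow_mode \code{"fixed_delay"} (reschedule exactly
#'   \code{delta_noshow} days later) or \code{"window"} (within
#'   \code{delta_max} days).
#' @param eq29_window recovery-window anchoring for emergency reschedules:
#'   \code{"printed"} anchors at each nominal day, \code{"rs_day"} at the
#'   disrupted day.
#' @return a \code{milp_model}.
#' @export
build_complete_model <- function(instance, penalties = NULL,
                                 noshow_mode = c("fixed_delay", "window"),
                                 eq29_window = c("printed", "rs_day")) {
  noshow_mode <- match.arg(noshow_mode)
  eq29_window <- match.arg(eq29_window)
  if (noshow_mode == "fixed_delay" &&
      instance$rs_days + instance$delta_noshow > instance$horizon_days)
    stop("fixed-delay no-show reschedule day falls outside the horizon")
  m <- new_model(instance, penalties)
  dm <- .dims(m)
  with(dm, {
    nB <- nI
    .add_var_family(m, "x",   c(nI, nD, nJ), "B")
    .add_var_family(m, "y",   c(nI, nW, nJ, nS), "B")
    .add_var_family(m, "nu",  c(nI, nI, nW, nJ), "B")
    .add_var_family(m, "xi",  c(nI, nW, nJ), "C", lb = 0, ub = max(Tc) + 1)
    .add_var_family(m, "C",   c(nW, nJ), "C", lb = 0, ub = max(Tc) + 1)
    .add_var_family(m, "rho", c(nH, nW, nJ), "B")
    .add_var_family(m, "lam", c(nI, nW, nJ, nH), "B")
    .add_var_family(m, "Xi",  c(nH, nW, nJ), "C", lb = 0, ub = max(Tc) + 1)
    .add_var_family(m, "eta", c(nH, nW, nJ), "B")
    .add_var_family(m, "chi", c(nH, nW, nI), "B")
    .add_var_family(m, "xbar", c(nH, nW, nL, nI, nD, nJ), "B")
    .add_var_family(m, "mu",  c(nH, nW, nL, nI), "B")
    .add_var_family(m, "theta", c(nI, nW, nJ), "B")
    .add_var_family(m, "xhat", c(nB, nW, nI, nD, nJ), "B")
    .add_var_family(m, "subact", c(nB, nW, nI, nJ), "B")
    # no self-precedence
    dg <- .eg(i = 1:nI, g = 1:nW, j = 1:nJ)
    m$ub[vid(m, "nu", dg$i, dg$i, dg$g, dg$j)] <- 0
  })
  .block_A(m); .block_B(m); .block_C(m); .block_D(m)
  .block_E(m, eq29_window); .block_F(m); .block_GH(m, noshow_mode)
  m$noshow_mode <- noshow_mode
  set_objective(m, "nominal")
  m
}

#' Enumerate disruption scenarios
#'
#' Emergency scenarios are all triples (moment h, protected day g, length
#' class l); no-show scenarios are pairs (patient b, protected day g) for
#' every patient compatible with some OR on day g (restriction to patients
#' actually scheduled on g is enforced inside the model, not by pruning).
#'
#' @param instance an \code{or_instance}.
#' @return list with data.frames \code{emergency} (h, g, l) and
#'   \code{noshow} (b, g).
#' @export
enumerate_scenarios <- function(instance) {
  H <- emergency_moments(instance)
  L <- seq_along(instance$emergency_classes)
  W <- seq_len(instance$rs_days)
  em <- .eg(h = H, g = W, l = L)
  nI <- nrow(instance$patients)
  ns <- .eg(b = seq_len(nI), g = W)
  keep <- vapply(seq_len(nrow(ns)), function(r)
    any(instance$compatibility[ns$b[r], ns$g[r], ] == 1), logical(1))
  list(emergency = em, noshow = ns[keep, , drop = FALSE])
}

#' Attach an auxiliary (heuristic) constraint block
#'
#' Block \code{"i"} adds day-difference variables and the two inequality
#' families tying them to a reference assignment; block \code{"ii"} pins the
#' protected-day admissions of the reference solution (with \code{>=}, so
#' additional admissions remain possible); block \code{"iii"} fixes the
#' reference ordering and OR assignment.
#'
#' @param m a \code{milp_model} containing the referenced variables.
#' @param block_id \code{"i"}, \code{"ii"} or \code{"iii"}.
#' @param reference for \code{"i"}/\code{"ii"}: the nominal assignment array
#'   x* (patients x days x ORs); for \code{"iii"}: the ordering array y*
#'   (patients x protected days x ORs x positions).
#' @return the model, invisibly.
#' @export
attach_auxiliary_block <- function(m, block_id = c("i", "ii", "iii"), reference) {
  block_id <- match.arg(block_id)
  if (block_id %in% m$blocks) stop("block ", block_id, " already attached")
  if (missing(reference) || is.null(reference))
    stop("auxiliary block ", block_id, " requires a stored reference solution")
  dm <- .dims(m)
  with(dm, {
    if (block_id == "i") {
      .add_var_family(m, "xdiff", c(nI, nD), "B")
      Xs <- apply(reference, c(1, 2), sum)          # sum over ORs
      gi <- .eg(i = 1:nI, d = 1:nD)
      nr <- nrow(gi)
      row <- seq_len(nr); col <- vid(m, "xdiff", gi$i, gi$d)
      coef <- rep(-1, nr)
      for (j in 1:nJ) {
        row <- c(row, seq_len(nr))
        col <- c(col, vid(m, "x", gi$i, gi$d, rep(j, nr)))
        coef <- c(coef, rep(1, nr))
      }
      .add_cons(m, "eq51", row, col, coef, "<=", Xs[cbind(gi$i, gi$d)])
      .add_cons(m, "eq52", row, col, c(rep(-1, nr), rep(-1, length(col) - nr)),
                "<=", -Xs[cbind(gi$i, gi$d)])
    } else if (block_id == "ii") {
      Xs <- apply(reference, c(1, 2), sum)
      gii <- .eg(i = 1:nI, g = 1:nW)
      nr <- nrow(gii)
      row <- integer(0); col <- integer(0)
      for (j in 1:nJ) {
        row <- c(row, seq_len(nr))
        col <- c(col, vid(m, "x", gii$i, gii$g, rep(j, nr)))
      }
      .add_cons(m, "eq50", row, col, rep(1, length(col)), ">=",
                Xs[cbind(gii$i, gii$g)])
    } else {
      ones <- which(reference == 1, arr.ind = TRUE)
      if (nrow(ones))
        m$lb[vid(m, "y", ones[, 1], ones[, 2], ones[, 3], ones[, 4])] <- 1
      .mark_bounds_family(m, "eq55")
    }
  })
  m$blocks <- c(m$blocks, block_id)
  invisible(m)
}

#' Select the active objective
#'
#' \code{"nominal"}: urgency-weighted waiting/tardiness penalties of the
#' nominal assignment (plus exclusion penalties).  \code{"difference"}:
#' number of patient-day differences from the stored reference (requires
#' block \code{"i"}).  \code{"emergency"}: scenario-average of the nominal
#' penalty functional over all emergency reschedules.  \code{"noshow"}:
#' the analogous average over no-show reschedules, scaled by the printed
#' normalization |D|/|I| (overridable via \code{noshow_norm}).
#'
#' @param m a \code{milp_model}.
#' @param kind objective id.
#' @param noshow_norm optional positive scalar replacing the printed
#'   1/(|I|/|D|) factor.
#' @return the model, invisibly.
#' @export
set_objective <- function(m, kind = c("nominal", "difference", "emergency", "noshow"),
                          noshow_norm = NULL) {
  kind <- match.arg(kind)
  dm <- .dims(m)
  p <- m$pen$p; q <- m$pen$q
  m$obj <- numeric(m$nvar)
  m$obj_const <- 0
  with(dm, {
    if (kind == "nominal") {
      g <- .eg(i = 1:nI, d = 1:nD, j = 1:nJ)
      m$obj[vid(m, "x", g$i, g$d, g$j)] <- p[cbind(g$i, g$d)] - q[g$i]
      m$obj_const <- sum(q)
    } else if (kind == "difference") {
      if (!("i" %in% m$blocks)) stop("objective 'difference' requires block i")
      fam <- m$vars[["xdiff"]]
      m$obj[fam$offset + seq_len(prod(fam$dim))] <- 1
    } else if (kind == "emergency") {
      if (is.null(m$vars[["xbar"]])) stop("model has no emergency plan variables")
      N <- nH * nW * nL
      g <- .eg(h = 1:nH, g = 1:nW, l = 1:nL, i = 1:nI, d = 1:nD, j = 1:nJ)
      m$obj[vid(m, "xbar", g$h, g$g, g$l, g$i, g$d, g$j)] <-
        (p[cbind(g$i, g$d)] - q[g$i]) / N
      m$obj_const <- sum(q)
    } else {
      if (is.null(m$vars[["xhat"]])) stop("model has no no-show plan variables")
      nB <- nI
      norm <- if (is.null(noshow_norm)) nD / nI else noshow_norm
      g <- .eg(b = 1:nB, g = 1:nW, i = 1:nI, d = 1:nD, j = 1:nJ)
      m$obj[vid(m, "xhat", g$b, g$g, g$i, g$d, g$j)] <-
        norm * (p[cbind(g$i, g$d)] - q[g$i])
      m$obj_const <- norm * nB * nW * sum(q)
    }
  })
  m$objective_id <- kind
  invisible(m)
}

#' Constraint-family audit
#'
#' @param m a \code{milp_model}.
#' @return named list mapping equation family ids to row counts,
#'   \code{"bounds"} for families realized as variable bounds, or an alias
#'   marker.
#' @export
model_families <- function(m) m$families

#' @export
print.milp_model <- function(x, ...) {
  cat(sprintf("<milp_model> %d vars, %d constraint rows, objective '%s'\n",
              x$nvar, x$ncon, x$objective_id))
  invisible(x)
}
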