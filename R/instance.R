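#' @importFrom stats runif setNames
#' @importFrom utils read.csv write.csv
NULL

#' Exact urgency coefficient
#'
#' The clinical urgency weight of a patient is \code{360 / li}, where
#' \code{li} is the surgical deadline in days (the clinically recommended
#' maximum time between list insertion and surgery).  The value is returned
#' as an exact reduced fraction so that \code{ui * li == 360} holds without
#' floating-point truncation even when \code{li} does not divide 360.
#'
#' @param li positive integer deadline, in days.
#' @return an object of class \code{rational} with fields \code{num} and
#'   \code{den}; coerce with \code{as.numeric()}.
#' @examples
#' as.numeric(urgency_coefficient(30))   # 12
#' urgency_coefficient(7)                # 360/7, exact
#' @export
urgency_coefficient <- function(li) {
  if (length(li) != 1L || !is.finite(li) || li <= 0 || li != as.integer(li))
    stop("deadline 'li' must be a single positive integer (days)")
  li <- as.integer(li)
  g <- .gcd(360L, li)
  structure(list(num = 360L %/% g, den = li %/% g), class = "rational")
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
print.rational <- function(x, ...) {
  if (x$den == 1L) cat(x$num, "\n") else cat(x$num, "/", x$den, "\n")
  invisible(x)
}

#' Waiting-list penalties
#'
#' Scheduling patient \code{i} on day \code{d} incurs penalty
#' \code{(d + max(mi + d - li, 0)) * ui}: the days until surgery plus any
#' tardiness beyond the clinical deadline, both weighted by the urgency
#' coefficient \code{ui = 360/li}.  Leaving a patient off the plan incurs
#' \code{(mi + |D| + 1 + max(mi + |D| + 1 - li, 0)) * ui}, which always
#' exceeds the penalty of any in-horizon day, so exclusion is never cheaper
#' than scheduling.
#'
#' With \code{weighting = "tardiness_only"} the urgency weight multiplies
#' only the tardiness term (an alternative reading of the penalty
#' definition, exposed for sensitivity analysis): \code{d + max(.,0)*ui}.
#'
#' @param mi days already spent on the waiting list (non-negative integer).
#' @param li clinical deadline in days.
#' @param d candidate day, 1-based, within the horizon.
#' @param horizon_days number of days in the planning horizon.
#' @param weighting \code{"full"} (default) or \code{"tardiness_only"}.
#' @return a single numeric penalty.
#' @examples
#' assignment_penalty(mi = 28, li = 30, d = 5)   # (5 + 3) * 12 = 96
#' exclusion_penalty(mi = 0, li = 360, horizon_days = 2)  # 3
#' @export
assignment_penalty <- function(mi, li, d, weighting = c("full", "tardiness_only")) {
  weighting <- match.arg(weighting)
  if (d < 1 || d != as.integer(d)) stop("day 'd' must be a positive integer")
  tard <- max(mi + d - li, 0)
  if (weighting == "full") (d + tard) * 360 / li else d + tard * 360 / li
}

#' @rdname assignment_penalty
#' @export
exclusion_penalty <- function(mi, li, horizon_days,
                              weighting = c("full", "tardiness_only")) {
  weighting <- match.arg(weighting)
  if (horizon_days < 1) stop("horizon must contain at least one day")
  base <- mi + horizon_days + 1
  tard <- max(base - li, 0)
  if (weighting == "full") (base + tard) * 360 / li else base + tard * 360 / li
}

#' Build the full penalty table for an instance
#'
#' @param instance an \code{or_instance}.
#' @param weighting see \code{\link{assignment_penalty}}.
#' @return list with matrix \code{p} (patients x days) and vector \code{q}.
#' @export
penalty_table <- function(instance, weighting = c("full", "tardiness_only")) {
  weighting <- match.arg(weighting)
  pat <- instance$patients
  nD <- instance$horizon_days
  p <- matrix(0, nrow(pat), nD)
  for (i in seq_len(nrow(pat)))
    for (d in seq_len(nD))
      p[i, d] <- assignment_penalty(pat$waited_days[i], pat$deadline_days[i], d,
                                    weighting)
  q <- vapply(seq_len(nrow(pat)), function(i)
    exclusion_penalty(pat$waited_days[i], pat$deadline_days[i], nD, weighting),
    numeric(1))
  # kept unnamed: named scalars leak out of matrix extraction and pollute
  # every downstream comparison; rows follow the instance's patient order
  structure(list(p = p, q = q, weighting = weighting), class = "penalty_table")
}

#' Maximum number of within-day positions
#'
#' An upper bound on how many surgeries can be sequenced in one OR-day:
#' \code{floor(max capacity / min duration)}, never below 1.
#'
#' @param instance an \code{or_instance}.
#' @return integer position count |S|.
#' @export
max_positions <- function(instance) {
  if (nrow(instance$patients) == 0L) stop("instance has no patients")
  max(1L, as.integer(floor(max(instance$capacity) /
                             min(instance$patients$duration_slots))))
}

#' Default patient-day-OR compatibility with weekends blocked
#'
#' Every (patient, day, OR) triple is compatible except days whose index is
#' a multiple of 6 or 7, which model the weekend of a working week starting
#' on day 1.
#'
#' @param n_patients,horizon_days,num_ors positive dimensions.
#' @return a 0/1 array of dim (patients, days, ORs).
#' @examples
#' a <- default_compatibility(2, 14, 2)
#' which(a[1, , 1] == 0)   # 6 7 12 14
#' @export
default_compatibility <- function(n_patients, horizon_days, num_ors) {
  if (n_patients < 1 || horizon_days < 1 || num_ors < 1)
    stop("dimensions must be positive")
  d <- seq_len(horizon_days)
  blocked <- (d %% 6L == 0L) | (d %% 7L == 0L)
  a <- array(1L, dim = c(n_patients, horizon_days, num_ors))
  a[, blocked, ] <- 0L
  a
}

#' @export
blocked_days <- function(horizon_days) {
  d <- seq_len(horizon_days)
  d[(d %% 6L == 0L) | (d %% 7L == 0L)]
}

#' Construct a scheduling instance
#'
#' @param patients data.frame with columns \code{id}, \code{duration_slots},
#'   \code{deadline_days}, \code{waited_days}.
#' @param horizon_days planning horizon |D| (days are 1-based).
#' @param num_ors number of operating rooms |J|.
#' @param rs_days number of leading days for which restoration schedules are
#'   built (|W|; the protected prefix of the horizon).
#' @param capacity slots per OR-day; scalar or a |D| x |J| matrix.
#' @param slot_minutes minutes per slot (15 by default).
#' @param overtime_slots recovery overtime allowance Omega, in slots.
#' @param delta_max maximum rescheduling delay Delta, in days.
#' @param delta_noshow fixed no-show rescheduling delay, in days.
#' @param emergency_classes slot durations of the emergency length classes.
#' @param epsilon strict-inequality constant in (0,1) used when deciding
#'   whether a surgery starts after an emergency moment.
#' @param big_m big-M constant; defaults to
#'   \code{max(slots-per-day, max capacity + overtime) + 1}.
#' @param compatibility 0/1 array (patients x days x ORs); defaults to
#'   \code{\link{default_compatibility}} (weekends blocked).
#' @return an object of class \code{or_instance}.
#' @export
new_instance <- function(patients, horizon_days, num_ors,
                         rs_days = 1L, capacity = 24L, slot_minutes = 15L,
                         overtime_slots = 4L, delta_max = 7L,
                         delta_noshow = 2L, emergency_classes = c(4L, 8L, 16L),
                         epsilon = 0.5, big_m = NULL, compatibility = NULL) {
  stopifnot(is.data.frame(patients),
            all(c("id", "duration_slots", "deadline_days", "waited_days")
                %in% names(patients)))
  patients$id <- as.character(patients$id)
  if (nrow(patients) == 0L) stop("instance has no patients")
  if (anyDuplicated(patients$id)) stop("patient ids must be unique")
  nI <- nrow(patients)
  horizon_days <- as.integer(horizon_days)
  num_ors <- as.integer(num_ors)
  rs_days <- as.integer(rs_days)
  if (length(capacity) == 1L)
    capacity <- matrix(as.integer(capacity), horizon_days, num_ors)
  capacity <- matrix(as.integer(capacity), horizon_days, num_ors)
  if (is.null(compatibility))
    compatibility <- default_compatibility(nI, horizon_days, num_ors)
  stopifnot(identical(dim(compatibility), c(nI, horizon_days, num_ors)))

  inst <- structure(list(
    patients = patients,
    horizon_days = horizon_days,
    num_ors = num_ors,
    rs_days = rs_days,
    capacity = capacity,
    slot_minutes = as.integer(slot_minutes),
    overtime_slots = as.integer(overtime_slots),
    delta_max = as.integer(delta_max),
    delta_noshow = as.integer(delta_noshow),
    emergency_classes = as.integer(emergency_classes),
    epsilon = epsilon,
    big_m = big_m,
    compatibility = compatibility
  ), class = "or_instance")
  if (is.null(big_m))
    inst$big_m <- max(max(inst$capacity), max(inst$capacity) +
                        inst$overtime_slots) + 1L
  validate_instance(inst)
  inst
}

#' Validate instance invariants
#'
#' Checks structural invariants: positive deadlines and durations, the
#' protected prefix fits the horizon, emergency classes fit the largest
#' OR-day, the no-show reschedule day exists, and compatibility is 0/1.
#'
#' @param inst an \code{or_instance}.
#' @return the instance, invisibly; stops on violation.
#' @export
validate_instance <- function(inst) {
  p <- inst$patients
  if (nrow(p) == 0L) stop("instance has no patients")
  if (any(p$deadline_days <= 0)) stop("deadlines li must be positive")
  if (any(p$waited_days < 0)) stop("waited days mi must be non-negative")
  if (any(p$duration_slots < 1)) stop("durations must be at least one slot")
  if (inst$rs_days < 1 || inst$rs_days > inst$horizon_days)
    stop("rs_days must be a non-empty prefix of the horizon")
  if (any(inst$capacity < 1)) stop("capacities must be at least one slot")
  if (any(inst$emergency_classes < 1) ||
      any(inst$emergency_classes > max(inst$capacity)))
    stop("emergency classes must fit within the largest OR-day")
  if (inst$delta_noshow < 1)
    stop("delta_noshow must be at least one day (the substitute comes from day g+1)")
  if (inst$delta_noshow > inst$delta_max)
    stop("fixed no-show delay cannot exceed the maximum rescheduling delay")
  if (inst$rs_days + inst$delta_noshow > inst$horizon_days)
    stop("no-show reschedule day g + delta_noshow falls outside the horizon")
  if (!all(inst$compatibility %in% c(0L, 1L)))
    stop("compatibility must be 0/1")
  hmax <- max(inst$capacity)
  if (inst$big_m < max(hmax, hmax + inst$overtime_slots) + 1L)
    stop("big_m too small for the model's disjunctions")
  invisible(inst)
}

#' Emergency moments of a protected day
#'
#' Slots at which an emergency may arrive: 0-based indices 0 .. T-1 where T
#' is the largest capacity on the protected days.  Note the convention
#' split: emergency moments are 0-based, surgery start slots are 1-based.
#'
#' @param inst an \code{or_instance}.
#' @export
emergency_moments <- function(inst) {
  Tm <- max(inst$capacity[seq_len(inst$rs_days), , drop = FALSE])
  0:(Tm - 1L)
}

# ---- serialization ---------------------------------------------------------

#' Read / write the canonical instance JSON
#'
#' The JSON layout is stable: top-level fields \code{horizon_days},
#' \code{num_ors}, \code{rs_days}, \code{slot_minutes}, \code{capacity}
#' (|D| x |J|), \code{overtime_slots}, \code{delta_max}, \code{delta_noshow},
#' \code{emergency_classes}, \code{epsilon} and a \code{patients} array with
#' \code{id}, \code{duration_slots}, \code{deadline_days}, \code{waited_days},
#' \code{compatible_days}, \code{compatible_ors} per patient.  A patient is
#' compatible with (d, j) iff d is in their \code{compatible_days} and j in
#' their \code{compatible_ors}.
#'
#' @param path file path.
#' @param inst an \code{or_instance}.
#' @return \code{read_instance} returns an \code{or_instance};
#'   \code{write_instance} returns \code{path} invisibly.
#' @export
write_instance <- function(inst, path) {
  pats <- lapply(seq_len(nrow(inst$patients)), function(i) {
    cd <- which(apply(inst$compatibility[i, , , drop = FALSE] == 1, 2, any))
    co <- which(apply(inst$compatibility[i, , , drop = FALSE] == 1, 3, any))
    list(id = inst$patients$id[i],
         duration_slots = inst$patients$duration_slots[i],
         deadline_days = inst$patients$deadline_days[i],
         waited_days = inst$patients$waited_days[i],
         compatible_days = as.integer(cd),
         compatible_ors = as.integer(co))
  })
  obj <- list(horizon_days = inst$horizon_days, num_ors = inst$num_ors,
              rs_days = inst$rs_days, slot_minutes = inst$slot_minutes,
              capacity = inst$capacity, overtime_slots = inst$overtime_slots,
              delta_max = inst$delta_max, delta_noshow = inst$delta_noshow,
              emergency_classes = inst$emergency_classes,
              epsilon = inst$epsilon, patients = pats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_instance
#' @export
read_instance <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  pats <- obj$patients
  df <- data.frame(
    id = vapply(pats, function(p) as.character(p$id), character(1)),
    duration_slots = vapply(pats, function(p) as.integer(p$duration_slots), integer(1)),
    deadline_days = vapply(pats, function(p) as.integer(p$deadline_days), integer(1)),
    waited_days = vapply(pats, function(p) as.integer(p$waited_days), integer(1)),
    stringsAsFactors = FALSE)
  nI <- nrow(df); nD <- as.integer(obj$horizon_days); nJ <- as.integer(obj$num_ors)
  a <- array(0L, dim = c(nI, nD, nJ))
  for (i in seq_len(nI)) {
    cd <- as.integer(unlist(pats[[i]]$compatible_days))
    co <- as.integer(unlist(pats[[i]]$compatible_ors))
    a[i, cd, co] <- 1L
  }
  new_instance(df, nD, nJ,
               rs_days = as.integer(obj$rs_days),
               capacity = matrix(as.integer(unlist(obj$capacity)), nD, nJ),
               slot_minutes = as.integer(obj$slot_minutes),
               overtime_slots = as.integer(obj$overtime_slots),
               delta_max = as.integer(obj$delta_max),
               delta_noshow = as.integer(obj$delta_noshow),
               emergency_classes = as.integer(unlist(obj$emergency_classes)),
               epsilon = as.numeric(obj$epsilon),
               compatibility = a)
}

#' Read a plain CSV waiting list
#'
#' Columns: \code{id,duration_slots,deadline_days,waited_days}.  Combine
#' with \code{\link{new_instance}} to obtain a full instance.
#'
#' @param path CSV file path.
#' @return a patients data.frame.
#' @examples
#' wl <- read_waiting_list(system.file("extdata", "example_waiting_list.csv",
#'                                     package = "surgsched"))
#' inst <- new_instance(wl, horizon_days = 14, num_ors = 2)
#' @export
read_waiting_list <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "duration_slots", "deadline_days", "waited_days")
  if (!all(need %in% names(df)))
    stop("waiting list CSV must have columns ", paste(need, collapse = ","))
  df[need]
}

#' @export
print.or_instance <- function(x, ...) {
  cat(sprintf(
    "<or_instance> %d patients, %d days x %d ORs, RS days 1..%d\n",
    nrow(x$patients), x$horizon_days, x$num_ors, x$rs_days))
  cat(sprintf("  capacity %d-%d slots (%d min), overtime %d, delta %d/%d, emergencies [%s]\n",
              min(x$capacity), max(x$capacity), x$slot_minutes,
              x$overtime_slots, x$delta_noshow, x$delta_max,
              paste(x$emergency_classes, collapse = ",")))
  invisible(x)
}
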