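# Synthetic waiting-list instance generation.
#
# The generator emulates the benchmark design used to exercise the model:
# waiting lists of 40/80/120 patients over 14- or 28-day horizons with 2-3
# ORs, 24 slots of 15 minutes per OR-day, weekends blocked, five urgency
# classes tied to Italian surgical-priority deadlines, and four surgical-
# length mixes (A short-skewed, B long-skewed, C uniform, D bimodal) plus a
# 54-patient case-study mix skewed toward the most urgent classes.

#' Surgical-length mixes
#'
#' Categorical distributions over surgery durations (in 15-minute slots)
#' for the four benchmark patient populations and the case-study list.  The
#' published histograms are not numerically tabulated, so these ship as
#' documented defaults and every one of them is overridable via
#' \code{generator_config}.
#'
#' @param mix one of \code{"A"}, \code{"B"}, \code{"C"}, \code{"D"},
#'   \code{"case_study"}.
#' @return named numeric vector: names are slot counts, values probabilities.
#' @export
duration_mix <- function(mix = c("A", "B", "C", "D", "case_study")) {
  mix <- match.arg(mix)
  m <- switch(mix,
    # short-skewed: mostly brief day-hospital procedures
    A = c(`2` = .30, `3` = .25, `4` = .20, `6` = .15, `8` = .10),
    # long-skewed: heavier procedures dominate
    B = c(`4` = .10, `6` = .15, `8` = .20, `10` = .25, `12` = .20, `16` = .10),
    # uniform over a broad range
    C = setNames(rep(1 / 6, 6), c(2, 4, 6, 8, 10, 12)),
    # bimodal: very short cases plus a long tail
    D = c(`2` = .25, `3` = .20, `4` = .10, `10` = .15, `12` = .20, `16` = .10),
    case_study = c(`2` = .20, `3` = .20, `4` = .20, `6` = .20, `8` = .15, `12` = .05))
  m / sum(m)
}

#' Urgency-class distributions
#'
#' Five urgency classes (i most urgent .. v least urgent) with default
#' deadlines 30/60/90/180/360 days.  The benchmark share is common to all
#' mixes; the case-study list has a larger share of very urgent patients.
#'
#' @param kind \code{"benchmark"} or \code{"case_study"}.
#' @return numeric vector of 5 class probabilities.
#' @export
urgency_mix <- function(kind = c("benchmark", "case_study")) {
  kind <- match.arg(kind)
  switch(kind,
         benchmark  = c(i = .10, ii = .20, iii = .30, iv = .25, v = .15),
         case_study = c(i = .30, ii = .25, iii = .20, iv = .15, v = .10))
}

#' Default urgency-class deadlines (days)
#' @export
urgency_deadlines <- function() c(i = 30L, ii = 60L, iii = 90L, iv = 180L, v = 360L)

#' Generator configuration
#'
#' @param n_patients waiting-list size.
#' @param horizon_days planning horizon (14 or 28 in the benchmark design).
#' @param num_ors number of ORs (2 or 3 in the benchmark design).
#' @param mix surgical-length mix label; see \code{\link{duration_mix}}.
#' @param seed integer RNG seed; a fixed seed yields a byte-identical
#'   instance.
#' @param duration_probs,urgency_probs,deadlines optional overrides of the
#'   mix defaults.
#' @param waited_frac upper fraction of the deadline used when sampling days
#'   already waited: \code{mi ~ Uniform{0 .. ceil(waited_frac * li)}}, so
#'   some patients are near-tardy and the tardiness terms are exercised.
#' @param rs_days,capacity,overtime_slots,delta_max,delta_noshow,emergency_classes
#'   instance parameters passed through to \code{\link{new_instance}};
#'   defaults are the benchmark settings (24 slots, Omega 4, Delta 7,
#'   no-show delay 2, emergency classes 4/8/16 slots).
#' @return a \code{generator_config} list.
#' @export
generator_config <- function(n_patients = 40L, horizon_days = 14L,
                             num_ors = 2L,
                             mix = c("A", "B", "C", "D", "case_study"),
                             seed = 1L,
                             duration_probs = NULL, urgency_probs = NULL,
                             deadlines = NULL, waited_frac = 0.8,
                             rs_days = 1L, capacity = 24L,
                             overtime_slots = 4L, delta_max = 7L,
                             delta_noshow = 2L,
                             emergency_classes = c(4L, 8L, 16L)) {
  mix <- match.arg(mix)
  if (is.null(duration_probs)) duration_probs <- duration_mix(mix)
  if (is.null(urgency_probs))
    urgency_probs <- urgency_mix(if (mix == "case_study") "case_study" else "benchmark")
  if (is.null(deadlines)) deadlines <- urgency_deadlines()
  stopifnot(abs(sum(duration_probs) - 1) < 1e-9,
            abs(sum(urgency_probs) - 1) < 1e-9,
            length(urgency_probs) == length(deadlines))
  durs <- as.integer(names(duration_probs))
  if (any(durs < 1)) stop("durations must be at least one slot")
  if (any(durs > max(capacity)))
    stop("duration distribution support exceeds OR capacity")
  structure(list(n_patients = as.integer(n_patients),
                 horizon_days = as.integer(horizon_days),
                 num_ors = as.integer(num_ors), mix = mix,
                 seed = as.integer(seed),
                 duration_probs = duration_probs,
                 urgency_probs = urgency_probs, deadlines = deadlines,
                 waited_frac = waited_frac, rs_days = as.integer(rs_days),
                 capacity = capacity, overtime_slots = overtime_slots,
                 delta_max = delta_max, delta_noshow = delta_noshow,
                 emergency_classes = emergency_classes),
            class = "generator_config")
}

#' Generate a synthetic waiting-list instance
#'
#' Samples patients i.i.d. from the configured duration and urgency
#' distributions, draws days-already-waited uniformly below the deadline,
#' applies the weekend compatibility mask, and assembles a full
#' \code{or_instance}.  Deterministic under the config seed (a private RNG
#' stream is used; the caller's RNG state is untouched).
#'
#' @param config a \code{generator_config}.
#' @return an \code{or_instance}.
#' @examples
#' inst <- generate_instance(generator_config(n_patients = 10, seed = 42))
#' inst
#' @export
generate_instance <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed, kind = "Mersenne-Twister")

  n <- config$n_patients
  durs <- as.integer(names(config$duration_probs))
  duration <- sample(durs, n, replace = TRUE, prob = config$duration_probs)
  cls <- sample(seq_along(config$urgency_probs), n, replace = TRUE,
                prob = config$urgency_probs)
  li <- as.integer(config$deadlines[cls])
  mi <- vapply(li, function(l)
    sample.int(ceiling(config$waited_frac * l) + 1L, 1L) - 1L, integer(1))
  patients <- data.frame(id = sprintf("P%03d", seq_len(n)),
                         duration_slots = duration,
                         deadline_days = li,
                         waited_days = mi,
                         urgency_class = names(config$urgency_probs)[cls],
                         stringsAsFactors = FALSE)
  new_instance(patients, config$horizon_days, config$num_ors,
               rs_days = config$rs_days, capacity = config$capacity,
               overtime_slots = config$overtime_slots,
               delta_max = config$delta_max,
               delta_noshow = config$delta_noshow,
               emergency_classes = config$emergency_classes)
}

#' Case-study instance: 54 ideal day-hospital patients
#'
#' A 54-patient waiting list with the case-study surgical mix and an
#' urgency distribution skewed toward the most urgent classes, over a
#' 14- or 28-day horizon with 2 or 3 ORs.
#'
#' @param seed integer seed.
#' @param horizon_days 14 or 28.
#' @param num_ors 2 or 3.
#' @return an \code{or_instance}.
#' @export
case_study_instance <- function(seed = 1L, horizon_days = 14L, num_ors = 2L) {
  generate_instance(generator_config(n_patients = 54L,
                                     horizon_days = horizon_days,
                                     num_ors = num_ors, mix = "case_study",
                                     seed = seed))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
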