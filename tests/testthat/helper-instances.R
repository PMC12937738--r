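# Shared fixtures, built in code.

# Three patients, one OR, two 12-slot days: only one patient fits per day,
# so exactly one patient must be excluded.  The exhaustive optimum is 19
# (P1 day 1, P3 day 2, P2 excluded).
tiny_instance <- function() {
  pats <- data.frame(id = c("P1", "P2", "P3"),
                     duration_slots = c(8L, 10L, 8L),
                     deadline_days = c(30L, 360L, 180L),
                     waited_days = c(28L, 0L, 100L),
                     stringsAsFactors = FALSE)
  new_instance(pats, horizon_days = 2L, num_ors = 1L, capacity = 12L,
               emergency_classes = c(4L, 8L), delta_noshow = 1L,
               delta_max = 7L)
}

# Random tiny instances for oracle-vs-MILP equivalence.
random_tiny_instance <- function(seed) {
  set.seed(seed)
  nI <- sample(3:6, 1)
  nD <- 2L
  nJ <- sample(1:2, 1)
  pats <- data.frame(id = sprintf("P%d", seq_len(nI)),
                     duration_slots = sample(2:9, nI, replace = TRUE),
                     deadline_days = sample(c(30L, 60L, 90L, 180L, 360L),
                                            nI, replace = TRUE),
                     waited_days = integer(nI),
                     stringsAsFactors = FALSE)
  pats$waited_days <- vapply(pats$deadline_days, function(l)
    sample.int(l, 1L) - 1L, integer(1))
  new_instance(pats, horizon_days = nD, num_ors = nJ,
               capacity = sample(10:14, 1), emergency_classes = c(4L),
               delta_noshow = 1L, delta_max = 7L)
}

# Pipeline runs are expensive; cache bundles across test files.
.bundle_cache <- new.env(parent = emptyenv())

cached_bundle <- function(key, maker) {
  if (is.null(.bundle_cache[[key]])) .bundle_cache[[key]] <- maker()
  .bundle_cache[[key]]
}

tiny_bundle <- function(strategy = "heuristic") {
  cached_bundle(paste0("tiny_", strategy), function()
    full_pipeline(tiny_instance(),
                  solve_config(strategy, time_limit = 60, gap = 1e-6)))
}

# A small benchmark-style instance (14 days, 2 ORs, 24 slots) kept at 20
# patients so the complete model stays solvable at test time limits.
small_bench_instance <- function(seed = 1L, n = 20L, mix = "A") {
  generate_instance(generator_config(n_patients = n, horizon_days = 14L,
                                     num_ors = 2L, mix = mix, seed = seed))
}

bench_bundle <- function(seed = 1L, strategy = "warm_start") {
  cached_bundle(sprintf("bench_%d_%s", seed, strategy), function()
    full_pipeline(small_bench_instance(seed),
                  solve_config(strategy, time_limit = 60, gap = 0.05)))
}
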