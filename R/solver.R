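# Solver-backend contract.
#
# A backend receives a finalized model (sparse triplet constraint matrix,
# row/column bounds, objective, integrality) plus a time limit and relative
# gap, and returns status, incumbent, objective and dual bound.  The default
# backend hands the arrays to HiGHS through SciPy's MILP interface in a
# Python subprocess; arrays cross the process boundary as little-endian
# binary scratch files in a temporary directory.

#' Finalize a model into backend arrays
#'
#' @param m a \code{milp_model}.
#' @return list of numeric/integer vectors describing the MILP.
#' @export
finalize_model <- function(m) {
  list(nvar = m$nvar, ncon = m$ncon,
       ai = unlist(m$ci, use.names = FALSE),
       aj = unlist(m$cj, use.names = FALSE),
       ax = unlist(m$cx, use.names = FALSE),
       rlo = unlist(m$rlo, use.names = FALSE),
       rhi = unlist(m$rhi, use.names = FALSE),
       obj = m$obj, obj_const = m$obj_const,
       lb = m$lb, ub = m$ub,
       integrality = as.integer(m$vtype %in% c("B", "I")))
}

.python_bin <- function() {
  p <- Sys.getenv("SURGSCHED_PYTHON", "")
  if (nzchar(p)) p else Sys.which("python")
}

#' Solve a model with the HiGHS backend
#'
#' @param m a \code{milp_model}.
#' @param time_limit wall-clock limit in seconds for the backend.
#' @param gap relative MIP gap tolerance.
#' @param verbose print backend log.
#' @param relax solve the LP relaxation (integrality dropped).
#' @return a \code{milp_solution}: list with \code{status} (one of
#'   \code{"optimal"}, \code{"time_limit"}, \code{"infeasible"},
#'   \code{"unbounded"}, \code{"no_incumbent"}, \code{"error"}),
#'   \code{objective}, \code{bound}, \code{gap}, \code{x} (full variable
#'   vector or NULL), and \code{seconds}.
#' @export
solve_model <- function(m, time_limit = 900, gap = 1e-6, verbose = FALSE,
                        relax = FALSE) {
  fm <- finalize_model(m)
  if (relax) fm$integrality[] <- 0L
  dir <- tempfile("milp")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  wb <- function(name, x, what) {
    con <- file(file.path(dir, name), "wb")
    on.exit(close(con), add = TRUE)
    if (what == "d") writeBin(as.numeric(x), con, size = 8, endian = "little")
    else writeBin(as.integer(x), con, size = 4, endian = "little")
  }
  wb("obj.bin", fm$obj, "d"); wb("lb.bin", fm$lb, "d"); wb("ub.bin", fm$ub, "d")
  wb("intg.bin", fm$integrality, "i")
  wb("ai.bin", fm$ai - 1L, "i"); wb("aj.bin", fm$aj - 1L, "i")
  wb("ax.bin", fm$ax, "d")
  wb("rlo.bin", fm$rlo, "d"); wb("rhi.bin", fm$rhi, "d")
  jsonlite::write_json(list(nvar = fm$nvar, ncon = fm$ncon,
                            nnz = length(fm$ax),
                            time_limit = time_limit, mip_rel_gap = gap,
                            verbose = verbose),
                       file.path(dir, "problem.json"), auto_unbox = TRUE)
  script <- system.file("python", "milp_solve.py", package = "surgsched")
  if (!nzchar(script)) stop("bundled solver script not found")
  t0 <- Sys.time()
  out <- suppressWarnings(
    system2(.python_bin(), c(shQuote(script), shQuote(dir)),
            stdout = TRUE, stderr = TRUE))
  rc <- attr(out, "status") %||% 0L
  if (verbose && length(out)) cat(out, sep = "\n")
  if (rc != 0L || !file.exists(file.path(dir, "result.json")))
    stop("MILP backend failed:\n", paste(out, collapse = "\n"))
  res <- jsonlite::read_json(file.path(dir, "result.json"), simplifyVector = TRUE)
  x <- NULL
  if (isTRUE(res$has_x)) {
    con <- file(file.path(dir, "x.bin"), "rb")
    x <- readBin(con, "numeric", n = fm$nvar, size = 8, endian = "little")
    close(con)
  }
  status <- switch(as.character(res$status),
                   "0" = "optimal",
                   "1" = if (isTRUE(res$has_x)) "time_limit" else "no_incumbent",
                   "2" = "infeasible", "3" = "unbounded", "error")
  structure(list(
    status = status,
    objective = if (isTRUE(res$has_x)) res$fun + fm$obj_const else NA_real_,
    bound = if (is.null(res$bound) || !is.finite(res$bound)) NA_real_
            else res$bound + fm$obj_const,
    gap = res$gap %||% NA_real_,
    x = x,
    seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "milp_solution")
}

#' Extract a variable family from a solution as a (rounded) array
#'
#' @param m the model the solution came from.
#' @param sol a \code{milp_solution} with an incumbent.
#' @param name variable family name.
#' @param round round binaries/integers to nearest integer (default TRUE).
#' @return numeric array with the family's dimensions.
#' @export
solution_values <- function(m, sol, name, round = TRUE) {
  if (is.null(sol$x)) stop("solution has no incumbent")
  v <- .fam_values(m, name, sol$x)
  if (round) v <- base::round(v)
  v
}

#' @export
print.milp_solution <- function(x, ...) {
  cat(sprintf("<milp_solution> status=%s objective=%s bound=%s gap=%s (%.1fs)\n",
              x$status, format(x$objective), format(x$bound),
              format(x$gap), x$seconds))
  invisible(x)
}

#' Export a model as LP-format text (for inspection of small models)
#'
#' @param m a \code{milp_model}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_lp <- function(m, path) {
  fm <- finalize_model(m)
  vn <- paste0("v", seq_len(fm$nvar))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("Minimize", con)
  terms <- which(fm$obj != 0)
  writeLines(paste(" obj:", paste(sprintf("%+g %s", fm$obj[terms], vn[terms]),
                                  collapse = " ")), con)
  writeLines("Subject To", con)
  ord <- order(fm$ai)
  ai <- fm$ai[ord]; aj <- fm$aj[ord]; ax <- fm$ax[ord]
  starts <- c(1L, which(diff(ai) > 0) + 1L, length(ai) + 1L)
  rows <- unique(ai)
  for (k in seq_along(rows)) {
    r <- rows[k]
    sel <- starts[k]:(starts[k + 1L] - 1L)
    lhs <- paste(sprintf("%+g %s", ax[sel], vn[aj[sel]]), collapse = " ")
    lo <- fm$rlo[r]; hi <- fm$rhi[r]
    if (is.finite(lo) && is.finite(hi) && lo == hi)
      writeLines(sprintf(" c%d: %s = %g", r, lhs, lo), con)
    else {
      if (is.finite(hi)) writeLines(sprintf(" c%d: %s <= %g", r, lhs, hi), con)
      if (is.finite(lo)) writeLines(sprintf(" c%dl: %s >= %g", r, lhs, lo), con)
    }
  }
  writeLines("Bounds", con)
  for (v in seq_len(fm$nvar))
    writeLines(sprintf(" %g <= %s <= %g", fm$lb[v], vn[v], fm$ub[v]), con)
  ints <- which(fm$integrality == 1L)
  if (length(ints)) {
    writeLines("General", con)
    writeLines(paste(" ", paste(vn[ints], collapse = " ")), con)
  }
  writeLines("End", con)
  invisible(path)
}
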