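#' Solver configuration
#'
#' The integer linear programs of the founder-set pipeline are solved by an
#' exchangeable backend. The default backend is HiGHS, reached through
#' `scipy.optimize.milp` in a python subprocess; the objective value of a
#' proven-optimal solve is canonical while the particular variable
#' assignment may differ between co-optimal solutions.
#'
#' @param backend backend name; currently `"scipy-highs"`.
#' @param python path to the python interpreter (default: `python3` or
#'   `python` found on the PATH).
#' @param time_limit optional wall-clock cap in seconds; when hit, the
#'   best-effort solution found so far is returned with
#'   `status = "time_limit"`.
#' @return a `solver_config` list.
#' @export
solver_config <- function(backend = "scipy-highs", python = NULL,
                          time_limit = NULL) {
  if (!identical(backend, "scipy-highs"))
    stop("unknown solver backend: ", backend)
  if (is.null(python)) {
    python <- Sys.which("python3")
    if (!nzchar(python)) python <- Sys.which("python")
    if (!nzchar(python)) stop("no python interpreter found on PATH")
  }
  structure(list(backend = backend, python = python, time_limit = time_limit),
            class = "solver_config")
}

# Solve min/max c'x s.t. lhs <= Ax <= rhs, lb <= x <= ub, x integer.
# A is given as a triplet list(i, j, x) with 1-based indices.
# Returns list(status, objective, x, gap).
milp_solve <- function(obj, triplets, lhs, rhs, lb, ub,
                       maximize = FALSE, integer = TRUE, cfg = NULL) {
  if (is.null(cfg)) cfg <- solver_config()
  stopifnot(inherits(cfg, "solver_config"))
  ncol <- length(obj)
  stopifnot(length(lb) == ncol, length(ub) == ncol,
            length(lhs) == length(rhs))
  problem <- list(
    ncol = ncol,
    obj = as.numeric(obj),
    maximize = isTRUE(maximize),
    row = as.integer(triplets$i) - 1L,
    col = as.integer(triplets$j) - 1L,
    val = as.numeric(triplets$x),
    lhs = as.numeric(lhs),
    rhs = as.numeric(rhs),
    lb = as.numeric(lb),
    ub = as.numeric(ub),
    integrality = rep(as.integer(integer), ncol),
    time_limit = cfg$time_limit
  )
  infile <- tempfile("milp-", fileext = ".json")
  outfile <- tempfile("milp-", fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(problem, infile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  script <- system.file("python", "milp.py", package = "founderset",
                        mustWork = TRUE)
  status <- system2(cfg$python, c(shQuote(script), shQuote(infile),
                                  shQuote(outfile)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) && attr(status, "status") != 0L)
    stop("solver backend failed:\n", paste(status, collapse = "\n"))
  res <- jsonlite::read_json(outfile, simplifyVector = TRUE)
  if (identical(res$status, "infeasible"))
    return(list(status = "infeasible", objective = NA_real_, x = NULL,
                gap = NA_real_))
  if (!res$success && !identical(res$status, "time_limit"))
    stop("solver backend returned status '", res$status, "'")
  x <- res$x
  if (integer && !is.null(x)) x <- round(x)
  list(status = res$status,
       objective = if (is.null(res$objective)) NA_real_ else res$objective,
       x = x,
       gap = if (is.null(res$mip_gap)) NA_real_ else res$mip_gap)
}

# incremental triplet builder used by the ILP constructors
triplet_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$i <- list(); env$j <- list(); env$x <- list(); env$n <- 0L
  env$lhs <- list(); env$rhs <- list()
  add_row <- function(cols, coefs, lo, hi) {
    env$n <- env$n + 1L
    env$i[[env$n]] <- rep.int(env$n, length(cols))
    env$j[[env$n]] <- as.integer(cols)
    env$x[[env$n]] <- as.numeric(coefs)
    env$lhs[[env$n]] <- lo
    env$rhs[[env$n]] <- hi
    invisible(env$n)
  }
  collect <- function() {
    list(triplets = list(i = unlist(env$i), j = unlist(env$j),
                         x = unlist(env$x)),
         lhs = unlist(env$lhs), rhs = unlist(env$rhs), nrow = env$n)
  }
  list(add_row = add_row, collect = collect)
}
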