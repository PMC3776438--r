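#' Solve a small dense linear program with bounded variables
#'
#' Solves `max/min c'x` subject to `A x = b` and `lb <= x <= ub` with a
#' two-phase bounded-variable primal simplex (compiled; Bland's rule, so
#' degenerate flux balance problems terminate). Intended for the small LPs
#' of this package; genome-scale problems are better served by a dedicated
#' LP library.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A dense constraint matrix (m x n) of equality rows.
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds; entries may be `-Inf`/`Inf`.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol numeric feasibility/optimality tolerance.
#' @return list with `status` (one of `"optimal"`, `"infeasible"`,
#'   `"unbounded"`, `"maxiter"`), and for optimal solutions `x` and
#'   `objective` (on the original max/min scale).
#' @examples
#' # max x1 + x2 s.t. x1 + x2 <= 1 written as x1 + x2 + s = 1
#' lp_solve(c(1, 1, 0), matrix(c(1, 1, 1), 1, 3), 1,
#'          lb = c(0, 0, 0), ub = c(Inf, Inf, Inf))
#' @export
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  stopifnot(length(obj) == ncol(A), length(b) == nrow(A),
            length(lb) == ncol(A), length(ub) == ncol(A))
  if (any(lb > ub)) stop("lower bound exceeds upper bound")
  cc <- if (maximize) -as.numeric(obj) else as.numeric(obj)
  res <- .simplex_solve(cc, A, as.numeric(b), as.numeric(lb),
                        as.numeric(ub), tol = tol)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible",
                   "2" = "unbounded", "3" = "maxiter")
  if (status != "optimal")
    return(list(status = status, x = NULL, objective = NA_real_))
  list(status = "optimal", x = as.numeric(res$x),
       objective = if (maximize) -res$objective else res$objective)
}
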