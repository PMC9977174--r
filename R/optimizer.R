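#' Optimiser settings for the model fits
#'
#' Both estimation stages maximise their (penalised) log-likelihood with
#' bounded quasi-Newton optimisation (`L-BFGS-B`), run in segments so that
#' the objective can be recorded after every segment. Convergence is
#' declared when the relative objective improvement between consecutive
#' segments drops below `rel_tol`, or when the inner optimiser reports
#' convergence, whichever comes first.
#'
#' @param max_iter Total iteration budget across segments.
#' @param rel_tol Relative objective-change convergence threshold.
#' @param segment_iter Iterations per segment (one trace point each).
#' @param factr Accuracy factor of the `"lbfgsb"` inner optimiser
#'   (see [stats::optim()]); ignored by `"port"`.
#' @param method Inner optimiser: `"lbfgsb"` ([stats::optim()], default)
#'   or `"port"` ([stats::nlminb()]).
#' @param lmm Number of BFGS correction pairs retained by `"lbfgsb"`.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(max_iter = 2000L, rel_tol = 1e-9,
                        segment_iter = 250L, factr = 1e8,
                        method = c("lbfgsb", "port"), lmm = 20L) {
  stopifnot(max_iter >= 1, rel_tol > 0, segment_iter >= 1, factr > 0,
            lmm >= 1)
  method <- match.arg(method)
  structure(list(max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 segment_iter = as.integer(segment_iter), factr = factr,
                 method = method, lmm = as.integer(lmm)),
            class = "fit_control")
}

# Maximize an objective under box bounds. `fngr(par)` returns
# list(objective = <scalar>, gradient = <vector>); objective and
# gradient share most intermediates, so both are computed in one pass
# and cached for the optimizer's separate fn/gr calls at the same point.
# Internally minimizes the negative. Returns the solution, the objective
# trace (initial value + one entry per segment, non-decreasing up to
# line-search tolerance) and a convergence flag.
maximize_lbfgs <- function(par, fngr, lower = -Inf, upper = Inf,
                           control = fit_control()) {
  cache_par <- NULL
  cache_val <- NULL
  eval_at <- function(p) {
    if (is.null(cache_par) || !identical(p, cache_par)) {
      cache_val <<- fngr(p)
      cache_par <<- p
    }
    cache_val
  }
  nfn <- function(p) -eval_at(p)$objective
  ngr <- function(p) -eval_at(p)$gradient
  trace <- fngr(par)$objective
  iters <- 0L
  converged <- FALSE
  while (iters < control$max_iter) {
    seg <- min(control$segment_iter, control$max_iter - iters)
    if (control$method == "port") {
      res <- stats::nlminb(par, nfn, ngr, lower = lower, upper = upper,
                           control = list(iter.max = seg,
                                          eval.max = 4L * seg,
                                          rel.tol = control$rel_tol))
      par <- res$par
      obj <- -res$objective
      inner_done <- res$convergence == 0
    } else {
      res <- stats::optim(par, nfn, ngr, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = seg,
                                         factr = control$factr,
                                         lmm = control$lmm))
      par <- res$par
      obj <- -res$value
      inner_done <- res$convergence == 0
    }
    prev <- trace[length(trace)]
    trace <- c(trace, obj)
    iters <- iters + seg
    if (inner_done || abs(obj - prev) < control$rel_tol * (abs(obj) + 1)) {
      converged <- TRUE
      break
    }
  }
  list(par = par, objective = trace[length(trace)], trace = trace,
       iterations = iters, converged = converged)
}
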