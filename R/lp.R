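#' Linear programming kernel
#'
#' A dense, bounded-variable, two-phase revised simplex used by every
#' optimization step in the package (flux-consistency testing, model
#' extraction, flux balance analysis, cardinality minimization). Problems in
#' this package are small (tens to a few hundred variables), dense tableau
#' algebra is fast enough, and owning the kernel gives bit-reproducible
#' pivoting: entering variables are chosen by the largest reduced-cost
#' violation with ties broken by the smallest column index, and the rule
#' switches to Bland's rule after a fixed iteration count to rule out
#' cycling.
#'
#' Solves: min (or max) `obj %*% x` subject to `A x (sense) rhs` and
#' `lower <= x <= upper`. Senses may be `"="`, `"<="` or `">="` per row.
#' Bounds may be infinite.
#'
#' @param obj numeric objective coefficients, length `ncol(A)`.
#' @param A dense or sparse constraint matrix (coerced to dense).
#' @param rhs right-hand side, length `nrow(A)`.
#' @param sense character vector of row senses; default all `"="`.
#' @param lower,upper variable bounds.
#' @param maximize logical; maximize instead of minimize.
#' @param tol feasibility/pivot tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `objective`, and the primal solution `x`
#'   (structural variables only).
#' @keywords internal
lp_solve <- function(obj, A, rhs, sense = NULL, lower, upper,
                     maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  m <- nrow(A)
  n0 <- ncol(A)
  if (is.null(sense)) sense <- rep("=", m)
  stopifnot(length(obj) == n0, length(rhs) == m, length(sense) == m,
            length(lower) == n0, length(upper) == n0)
  if (any(lower > upper + 1e-9)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n0)))
  }
  ## slack variables for inequality rows
  ineq <- which(sense != "=")
  if (length(ineq)) {
    Sl <- matrix(0, m, length(ineq))
    slo <- shi <- numeric(length(ineq))
    for (k in seq_along(ineq)) {
      i <- ineq[k]
      Sl[i, k] <- 1
      if (sense[i] == "<=") {
        slo[k] <- 0; shi[k] <- Inf
      } else {
        slo[k] <- -Inf; shi[k] <- 0
      }
    }
    A <- cbind(A, Sl)
    lower <- c(lower, slo)
    upper <- c(upper, shi)
  }
  cost <- c(if (maximize) -obj else obj, rep(0, ncol(A) - n0))
  res <- .simplex_bounded(A, rhs, cost, lower, upper, tol = tol)
  obj_val <- if (res$status == "optimal") {
    v <- sum(cost * res$x)
    if (maximize) -v else v
  } else NA_real_
  list(status = res$status, objective = obj_val, x = res$x[seq_len(n0)])
}

## Bounded-variable two-phase revised simplex on equality form
## min cost'x, A x = b, lo <= x <= hi.
.simplex_bounded <- function(A, b, cost, lo, hi, tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)
  told <- 1e-7     # reduced-cost (dual) tolerance
  tolp <- 1e-9     # pivot tolerance
  feas <- 1e-7     # phase-1 feasibility tolerance

  ## nonbasic start values: finite bound nearest zero, free variables at 0
  start_val <- function(l, h) {
    if (is.finite(l) && is.finite(h)) (if (abs(l) <= abs(h)) l else h)
    else if (is.finite(l)) l
    else if (is.finite(h)) h
    else 0
  }
  x <- mapply(start_val, lo, hi)

  ## artificial variables, one per row, signed to make the start feasible
  r <- as.vector(b - A %*% x)
  sg <- ifelse(r >= 0, 1, -1)
  Aall <- cbind(A, diag(sg, nrow = m))
  lo <- c(lo, rep(0, m))
  hi <- c(hi, rep(Inf, m))
  x <- c(x, abs(r))
  ntot <- n + m
  art <- n + seq_len(m)

  basis <- art
  ## stat: 0 basic, 1 at lower, 2 at upper, 3 free at value
  stat <- integer(ntot)
  stat[seq_len(n)] <- ifelse(is.finite(lo[seq_len(n)]) &
                               x[seq_len(n)] == lo[seq_len(n)], 1L,
                      ifelse(is.finite(hi[seq_len(n)]) &
                               x[seq_len(n)] == hi[seq_len(n)], 2L, 3L))
  stat[art] <- 0L
  Binv <- diag(1 / sg, nrow = m)

  iter_total <- 0L
  itmax <- 200L + 40L * (n + m)
  bland_after <- 50L + 10L * (n + m)

  run_phase <- function(cvec, allow_enter) {
    repeat {
      iter_total <<- iter_total + 1L
      if (iter_total > itmax) return("iteration_limit")
      if (iter_total %% 80L == 0L) {
        ## refactorize for numerical hygiene
        Binv <<- tryCatch(solve(Aall[, basis, drop = FALSE]),
                          error = function(e) Binv)
        nb <- which(stat != 0L)
        x[basis] <<- as.vector(Binv %*%
          (b - Aall[, nb, drop = FALSE] %*% x[nb]))
      }
      y <- as.vector(crossprod(cvec[basis], Binv))
      nonb <- which(stat != 0L & allow_enter)
      if (!length(nonb)) return("optimal")
      d <- cvec[nonb] - as.vector(y %*% Aall[, nonb, drop = FALSE])
      st <- stat[nonb]
      viol <- ifelse(st == 1L, -d, ifelse(st == 2L, d, abs(d)))
      cand <- which(viol > told)
      if (!length(cand)) return("optimal")
      if (iter_total > bland_after) {
        k <- cand[1L]                       # Bland: smallest index
      } else {
        k <- cand[which.max(viol[cand])]    # Dantzig, ties -> smallest index
      }
      j <- nonb[k]
      dj <- d[k]
      dirn <- if (stat[j] == 1L) 1 else if (stat[j] == 2L) -1 else
        if (dj < 0) 1 else -1
      w <- as.vector(Binv %*% Aall[, j])
      delta <- dirn * w
      ## basic variable i moves as x[basis][i] - t * delta[i]
      tmax <- if (is.finite(lo[j]) && is.finite(hi[j])) hi[j] - lo[j] else Inf
      best_t <- tmax
      leave <- 0L
      leave_to <- 0L
      xb <- x[basis]
      for (i in seq_len(m)) {
        di <- delta[i]
        if (di > tolp) {
          li <- lo[basis[i]]
          if (is.finite(li)) {
            ti <- (xb[i] - li) / di
            if (ti < best_t - 1e-12 ||
                (ti < best_t + 1e-12 && leave > 0L &&
                 abs(di) > abs(delta[leave]))) {
              best_t <- ti; leave <- i; leave_to <- 1L
            }
          }
        } else if (di < -tolp) {
          ui <- hi[basis[i]]
          if (is.finite(ui)) {
            ti <- (xb[i] - ui) / di
            if (ti < best_t - 1e-12 ||
                (ti < best_t + 1e-12 && leave > 0L &&
                 abs(di) > abs(delta[leave]))) {
              best_t <- ti; leave <- i; leave_to <- 2L
            }
          }
        }
      }
      if (!is.finite(best_t)) return("unbounded")
      best_t <- max(best_t, 0)
      ## apply step
      x[basis] <<- x[basis] - best_t * delta
      x[j] <<- x[j] + dirn * best_t
      if (leave == 0L) {
        ## bound flip of the entering variable
        stat[j] <<- if (stat[j] == 1L) 2L else 1L
      } else {
        out <- basis[leave]
        stat[out] <<- leave_to
        x[out] <<- if (leave_to == 1L) lo[out] else hi[out]
        stat[j] <<- 0L
        basis[leave] <<- j
        ## eta update of Binv
        piv <- w[leave]
        Brow <- Binv[leave, ] / piv
        Binv <<- Binv - outer(w, Brow)
        Binv[leave, ] <<- Brow
      }
    }
  }

  ## phase 1: minimize sum of artificials
  c1 <- c(rep(0, n), rep(1, m))
  allow1 <- rep(TRUE, ntot)
  st1 <- run_phase(c1, allow1)
  if (st1 != "optimal") return(list(status = st1, x = x[seq_len(n)]))
  if (sum(x[art]) > feas) {
    return(list(status = "infeasible", x = x[seq_len(n)]))
  }
  ## pin artificials at zero and never let them re-enter
  lo[art] <- 0
  hi[art] <- 0
  x[art] <- pmax(0, pmin(x[art], 0))
  allow2 <- c(rep(TRUE, n), rep(FALSE, m))
  c2 <- c(cost, rep(0, m))
  st2 <- run_phase(c2, allow2)
  if (st2 != "optimal") return(list(status = st2, x = x[seq_len(n)]))
  ## clean tiny residuals
  xs <- x[seq_len(n)]
  xs[abs(xs) < 1e-11] <- 0
  list(status = "optimal", x = xs)
}

#' Mixed-integer programming by LP-based branch and bound
#'
#' Minimal branch-and-bound over binary variables on top of [lp_solve()],
#' used for the exact zero-norm (minimal-cardinality) flux route on small
#' models. Depth-first search, branching on the most fractional binary,
#' incumbent pruning with a small absolute gap.
#'
#' @inheritParams lp_solve
#' @param binary integer/logical index of variables constrained to {0,1}.
#' @param gap prune nodes whose LP bound is within `gap` of the incumbent.
#' @param node_limit abort (status `"node_limit"`) beyond this many nodes.
#' @return list with `status`, `objective`, `x`, `nodes`.
#' @keywords internal
milp_solve <- function(obj, A, rhs, sense = NULL, lower, upper, binary,
                       maximize = FALSE, gap = 1e-6, node_limit = 20000L) {
  if (is.logical(binary)) binary <- which(binary)
  sgn <- if (maximize) -1 else 1
  objm <- sgn * obj
  best <- list(objective = Inf, x = NULL)
  nodes <- 0L
  inttol <- 1e-6
  status <- "optimal"

  rec <- function(lo, hi) {
    if (nodes >= node_limit) {
      status <<- "node_limit"
      return(invisible(NULL))
    }
    nodes <<- nodes + 1L
    rel <- lp_solve(objm, A, rhs, sense, lo, hi, maximize = FALSE)
    if (rel$status != "optimal") return(invisible(NULL))
    if (rel$objective >= best$objective - gap) return(invisible(NULL))
    xb <- rel$x[binary]
    frac <- abs(xb - round(xb))
    if (all(frac <= inttol)) {
      best <<- list(objective = rel$objective, x = rel$x)
      return(invisible(NULL))
    }
    jb <- binary[which.max(frac)]
    ## branch down first (prefers sparse supports)
    lo0 <- lo; hi0 <- hi
    hi0[jb] <- 0
    rec(lo0, hi0)
    lo1 <- lo; hi1 <- hi
    lo1[jb] <- 1
    rec(lo1, hi1)
    invisible(NULL)
  }
  lo <- lower; hi <- upper
  lo[binary] <- pmax(lo[binary], 0)
  hi[binary] <- pmin(hi[binary], 1)
  rec(lo, hi)
  if (is.null(best$x)) {
    return(list(status = if (status == "node_limit") status else "infeasible",
                objective = NA_real_, x = NULL, nodes = nodes))
  }
  list(status = status, objective = sgn * best$objective, x = best$x,
       nodes = nodes)
}
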