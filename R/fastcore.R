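#' Flux-consistency testing and core-based model extraction
#'
#' `find_consistent_subnetwork()` implements a FASTCC-style consistency
#' test: a reaction is flux-consistent when some steady-state flux vector
#' within bounds carries at least `epsilon` absolute flux through it. The
#' algorithm solves a small number of LPs that jointly push many reactions
#' above the activation threshold (the LP7 program of the FASTCORE family),
#' flipping reversible candidates before giving up on them.
#'
#' `extract_core_subnetwork()` implements the FASTCORE extraction: given a
#' flux-consistent network and a core reaction set, it returns a compact
#' flux-consistent subnetwork containing every core reaction, adding as few
#' non-core reactions as possible (heuristically minimal, typically within
#' one reaction of the true minimum on small networks). Non-core additions
#' can be biased with per-reaction penalties.
#'
#' @name fastcore
NULL

## LP7: maximize the number of reactions in `Ji` carrying flux >= eps.
## Variables are the fluxes v plus one auxiliary z_k per target (0 <= z_k <=
## eps, z_k <= v_k); maximizing sum(z) saturates as many targets as possible.
lp7 <- function(S, lb, ub, Ji, eps) {
  m <- nrow(S); n <- ncol(S); nj <- length(Ji)
  A <- cbind(S, matrix(0, m, nj))
  extra <- matrix(0, nj, n + nj)
  extra[cbind(seq_len(nj), Ji)] <- 1
  extra[cbind(seq_len(nj), n + seq_len(nj))] <- -1
  A <- rbind(A, extra)
  res <- lp_solve(obj = c(rep(0, n), rep(1, nj)),
                  A = A, rhs = rep(0, m + nj),
                  sense = c(rep("=", m), rep(">=", nj)),
                  lower = c(lb, rep(0, nj)),
                  upper = c(ub, rep(eps, nj)),
                  maximize = TRUE)
  if (res$status != "optimal") {
    stop("flux LP failed (status ", res$status,
         "): network admits no steady state within bounds")
  }
  res$x[seq_len(n)]
}

## LP10: among flux vectors activating every reaction in K (v_k >= eps),
## minimize the weighted 1-norm of fluxes through the penalized set P.
lp10 <- function(S, lb, ub, K, P, eps, weights = NULL) {
  m <- nrow(S); n <- ncol(S); np <- length(P)
  if (is.null(weights)) weights <- rep(1, np)
  lbk <- lb
  lbk[K] <- pmax(lbk[K], eps)
  A <- cbind(S, matrix(0, m, np))
  if (np) {
    e1 <- matrix(0, np, n + np)  # z_p - v_p >= 0
    e1[cbind(seq_len(np), P)] <- -1
    e1[cbind(seq_len(np), n + seq_len(np))] <- 1
    e2 <- matrix(0, np, n + np)  # z_p + v_p >= 0
    e2[cbind(seq_len(np), P)] <- 1
    e2[cbind(seq_len(np), n + seq_len(np))] <- 1
    A <- rbind(A, e1, e2)
  }
  big <- max(abs(c(lb, ub, 1)))
  res <- lp_solve(obj = c(rep(0, n), weights),
                  A = A, rhs = rep(0, m + 2 * np),
                  sense = c(rep("=", m), rep(">=", 2 * np)),
                  lower = c(lbk, rep(0, np)),
                  upper = c(ub, rep(big, np)),
                  maximize = FALSE)
  if (res$status != "optimal") return(NULL)
  res$x[seq_len(n)]
}

#' @rdname fastcore
#' @param network a `metabolic_network`.
#' @param epsilon positive flux-activation threshold (a.u.); fluxes below it
#'   count as numerically zero. Default `1e-4`.
#' @return `find_consistent_subnetwork()` returns a `consistency_result`:
#'   list with `consistent_reactions`, `removed_reactions`, `epsilon`.
#' @export
find_consistent_subnetwork <- function(network, epsilon = 1e-4) {
  stopifnot(epsilon > 0)
  S <- as.matrix(network$S)
  lb <- network$rxns$lower
  ub <- network$rxns$upper
  n <- ncol(S)
  rid <- network$rxns$id
  irr <- which(lb >= 0)

  supp <- function(v) which(abs(v) >= epsilon * 0.99)

  A <- integer(0)
  J <- irr
  if (length(J)) {
    v <- lp7(S, lb, ub, J, epsilon)
    A <- supp(v)
  }
  ## irreversible reactions that LP7 could not activate are inconsistent
  J <- setdiff(seq_len(n), union(A, irr))
  J <- J[order(rid[J])]
  flipped <- FALSE
  singleton <- FALSE
  while (length(J)) {
    Ji <- if (singleton) J[1L] else J
    v <- lp7(S, lb, ub, Ji, epsilon)
    A <- union(A, supp(v))
    if (length(intersect(J, A))) {
      J <- setdiff(J, A)
      flipped <- FALSE
      singleton <- FALSE
    } else {
      JiRev <- setdiff(Ji, irr)
      if (flipped || !length(JiRev)) {
        flipped <- FALSE
        if (singleton) {
          J <- setdiff(J, Ji)   # inconsistent reaction, drop it
        } else {
          singleton <- TRUE
        }
      } else {
        S[, JiRev] <- -S[, JiRev]
        tmp <- lb[JiRev]
        lb[JiRev] <- -ub[JiRev]
        ub[JiRev] <- -tmp
        flipped <- TRUE
      }
    }
  }
  consistent <- sort(rid[sort(A)])
  structure(list(consistent_reactions = consistent,
                 removed_reactions = sort(setdiff(rid, consistent)),
                 epsilon = epsilon),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("consistency_result: %d consistent, %d removed (epsilon %g)\n",
              length(x$consistent_reactions), length(x$removed_reactions),
              x$epsilon))
  invisible(x)
}

#' @rdname fastcore
#' @param core character vector of core reaction ids; must be
#'   flux-consistent in `network`.
#' @param penalties optional named non-negative weights over non-core
#'   reactions (default 1 each); higher values discourage adding a reaction.
#' @param prune run the greedy redundancy prune after extraction (one
#'   consistency test per non-core addition). Defaults to `TRUE` for
#'   networks up to 30 reactions, where near-exact minimality is worth the
#'   extra LPs, and `FALSE` above that, where the plain extraction's
#'   heuristic compactness stands.
#' @return `extract_core_subnetwork()` returns the sorted character vector
#'   of reaction ids of the context-specific model (a superset of `core`).
#' @export
extract_core_subnetwork <- function(network, core, epsilon = 1e-4,
                                    penalties = NULL, prune = NULL) {
  if (is.null(prune)) prune <- nrow(network$rxns) <= 30
  stopifnot(epsilon > 0)
  rid <- network$rxns$id
  missing <- setdiff(core, rid)
  if (length(missing)) {
    stop("core reactions absent from network: ",
         paste(missing, collapse = ", "))
  }
  S <- as.matrix(network$S)
  lb <- network$rxns$lower
  ub <- network$rxns$upper
  n <- ncol(S)
  irr <- which(lb >= 0)
  C <- which(rid %in% core)
  w <- rep(1, n)
  if (!is.null(penalties)) {
    idx <- match(names(penalties), rid)
    if (anyNA(idx)) stop("penalty for unknown reaction: ",
                         paste(names(penalties)[is.na(idx)], collapse = ", "))
    w[idx] <- penalties
  }

  supp_tol <- max(1e-8, epsilon * 1e-3)

  find_sparse_mode <- function(J, P, singleton) {
    if (!length(J)) return(integer(0))
    Ji <- if (singleton) J[1L] else J
    v <- lp7(S, lb, ub, Ji, epsilon)
    K <- intersect(Ji, which(v >= epsilon * 0.99))
    if (!length(K)) return(integer(0))
    v <- lp10(S, lb, ub, K, P, epsilon, weights = w[P])
    if (is.null(v)) return(integer(0))
    which(abs(v) > supp_tol)
  }

  flipped <- FALSE
  singleton <- FALSE
  J <- intersect(C, irr)
  J <- J[order(rid[J])]
  P <- setdiff(seq_len(n), C)
  Supp <- find_sparse_mode(J, P, FALSE)
  if (length(setdiff(J, Supp))) {
    stop("core reactions cannot be activated: ",
         paste(sort(rid[setdiff(J, Supp)]), collapse = ", "))
  }
  A <- Supp
  J <- setdiff(C, A)
  J <- J[order(rid[J])]
  while (length(J)) {
    P <- setdiff(P, A)
    Supp <- find_sparse_mode(J, P, singleton)
    A <- union(A, Supp)
    if (length(intersect(J, A))) {
      J <- setdiff(J, A)
      flipped <- FALSE
      singleton <- FALSE
    } else {
      if (flipped) {
        flipped <- FALSE
        if (singleton) {
          stop("core reactions cannot be activated: ",
               rid[J[1L]])
        }
        singleton <- TRUE
      } else {
        JiRev <- setdiff(if (singleton) J[1L] else J, irr)
        if (!length(JiRev)) {
          if (singleton) {
            stop("core reactions cannot be activated: ", rid[J[1L]])
          }
          singleton <- TRUE
        } else {
          S[, JiRev] <- -S[, JiRev]
          tmp <- lb[JiRev]
          lb[JiRev] <- -ub[JiRev]
          ub[JiRev] <- -tmp
          flipped <- TRUE
        }
      }
    }
  }
  ## greedy prune: the LP7 step can pick a flux orientation that drags in a
  ## redundant branch; drop any non-core addition whose removal leaves a
  ## flux-consistent model still covering the core (lexicographic order,
  ## shrinking to the consistent part so removals can cascade)
  ## one pass is enough: the consistent part of a subset is a subset of the
  ## consistent part, so a reaction that cannot be dropped now never becomes
  ## droppable after further removals
  kept <- sort(rid[sort(A)])
  if (prune) {
    for (r in setdiff(kept, core)) {
      if (!r %in% kept) next      # already gone with an earlier shrink
      trial <- setdiff(kept, r)
      cp <- find_consistent_subnetwork(subnetwork(network, trial),
                                       epsilon)$consistent_reactions
      if (all(core %in% cp)) kept <- cp
    }
  }
  sort(kept)
}
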