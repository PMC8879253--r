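# Dense two-phase primal simplex for box-constrained linear programs:
#
#     max/min  c'v   subject to   A v = b,   lb <= v <= ub
#
# This is the LP core behind flux balance analysis in this package.  All
# bounds must be finite (flux bounds are).  Variables are shifted to
# x = v - lb >= 0 and finite upper bounds become explicit slack rows, so
# the working problem is a standard-form LP solved with a full tableau.
# Pivoting uses Dantzig's rule with an automatic switch to Bland's rule
# after a stall, which guarantees termination on degenerate problems.

.simplex_core <- function(Tm, basis, n_real, eps = 1e-9, max_iter = NULL) {
  m <- nrow(Tm) - 1L
  ncol_T <- ncol(Tm)
  if (is.null(max_iter)) max_iter <- 50L * (m + ncol_T)
  stall <- 0L
  last_obj <- Tm[m + 1L, ncol_T]
  for (it in seq_len(max_iter)) {
    cost <- Tm[m + 1L, -ncol_T]
    use_bland <- stall > 2L * m
    enter <- if (use_bland) {
      cand <- which(cost < -eps)
      if (length(cand)) cand[1L] else 0L
    } else {
      j <- which.min(cost)
      if (cost[j] < -eps) j else 0L
    }
    if (enter == 0L) return(list(T = Tm, basis = basis, status = "optimal"))
    col <- Tm[seq_len(m), enter]
    pos <- which(col > eps)
    if (!length(pos)) return(list(T = Tm, basis = basis, status = "unbounded"))
    ratios <- Tm[pos, ncol_T] / col[pos]
    rmin <- min(ratios)
    ties <- pos[ratios <= rmin + eps]
    # Bland tie-break: smallest basis index leaves
    leave <- ties[which.min(basis[ties])]
    piv <- Tm[leave, enter]
    Tm[leave, ] <- Tm[leave, ] / piv
    other <- setdiff(seq_len(m + 1L), leave)
    Tm[other, ] <- Tm[other, ] - outer(Tm[other, enter], Tm[leave, ])
    basis[leave] <- enter
    obj <- Tm[m + 1L, ncol_T]
    stall <- if (obj < last_obj - eps) 0L else stall + 1L
    last_obj <- obj
  }
  list(T = Tm, basis = basis, status = "iteration_limit")
}

#' Solve a box-constrained linear program
#'
#' @param obj objective coefficient vector (length n).
#' @param A constraint matrix (m x n) for `A v = b`.
#' @param b right-hand side (length m).
#' @param lb,ub finite lower/upper bounds on `v`.
#' @param maximize maximize (default) or minimize.
#' @param eps numerical tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `solution` (v at the optimum) and `objective`.
#' @export
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, eps = 1e-9) {
  n <- length(obj)
  stopifnot(ncol(A) == n, length(b) == nrow(A),
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite bounds")
  if (any(lb > ub + eps))
    return(list(status = "infeasible", solution = NULL, objective = NA_real_))
  m <- nrow(A)
  # shift x = v - lb
  b2 <- b - as.numeric(A %*% lb)
  u2 <- ub - lb
  # variables with zero range are constants: substitute out
  # (keep them as columns anyway; their ub row forces x = 0)
  k_idx <- which(is.finite(u2))
  k <- length(k_idx)
  # rows: m equality + k upper-bound rows
  M <- m + k
  Nv <- n + k                      # x's + upper-bound slacks
  Am <- matrix(0, M, Nv)
  Am[seq_len(m), seq_len(n)] <- A
  rhs <- c(b2, u2[k_idx])
  if (k) {
    Am[cbind(m + seq_len(k), k_idx)] <- 1
    Am[cbind(m + seq_len(k), n + seq_len(k))] <- 1
  }
  # normalise rows to non-negative rhs
  neg <- rhs < 0
  Am[neg, ] <- -Am[neg, , drop = FALSE]
  rhs[neg] <- -rhs[neg]
  # scale rows for conditioning
  rs <- pmax(apply(abs(Am), 1, max), 1e-12)
  Am <- Am / rs
  rhs <- rhs / rs

  cvec <- if (maximize) -c(obj, rep(0, k)) else c(obj, rep(0, k))

  # ---- phase 1
  Tm <- matrix(0, M + 1L, Nv + M + 1L)
  Tm[seq_len(M), seq_len(Nv)] <- Am
  Tm[cbind(seq_len(M), Nv + seq_len(M))] <- 1
  Tm[seq_len(M), Nv + M + 1L] <- rhs
  # phase-1 cost: sum of artificials, expressed in reduced form
  Tm[M + 1L, seq_len(Nv)] <- -colSums(Am)
  Tm[M + 1L, Nv + M + 1L] <- -sum(rhs)
  basis <- Nv + seq_len(M)
  r1 <- .simplex_core(Tm, basis, Nv, eps)
  if (r1$status != "optimal" || -r1$T[M + 1L, Nv + M + 1L] > 1e-7 * (1 + max(abs(rhs))))
    return(list(status = "infeasible", solution = NULL, objective = NA_real_))
  Tm <- r1$T; basis <- r1$basis
  # drive remaining artificials out of the basis where possible
  for (i in which(basis > Nv)) {
    row <- Tm[i, seq_len(Nv)]
    j <- which(abs(row) > eps)
    if (length(j)) {
      enter <- j[1L]
      piv <- Tm[i, enter]
      Tm[i, ] <- Tm[i, ] / piv
      other <- setdiff(seq_len(M + 1L), i)
      Tm[other, ] <- Tm[other, ] - outer(Tm[other, enter], Tm[i, ])
      basis[i] <- enter
    }
  }
  # rows still basic in an artificial are (numerically) redundant: drop them
  keep <- which(basis <= Nv)
  Tm2 <- Tm[c(keep, M + 1L), c(seq_len(Nv), Nv + M + 1L), drop = FALSE]
  basis2 <- basis[keep]
  M2 <- length(keep)
  # ---- phase 2: rebuild cost row over real columns only
  Tm2[M2 + 1L, ] <- 0
  Tm2[M2 + 1L, seq_len(Nv)] <- cvec
  for (i in seq_len(M2)) {
    if (abs(cvec[basis2[i]]) > 0)
      Tm2[M2 + 1L, ] <- Tm2[M2 + 1L, ] - cvec[basis2[i]] * Tm2[i, ]
  }
  r2 <- .simplex_core(Tm2, basis2, Nv, eps)
  if (r2$status == "unbounded")
    return(list(status = "unbounded", solution = NULL, objective = NA_real_))
  if (r2$status != "optimal")
    return(list(status = "iteration_limit", solution = NULL, objective = NA_real_))
  Tm2 <- r2$T; basis2 <- r2$basis
  x <- numeric(Nv)
  x[basis2] <- Tm2[seq_len(M2), Nv + 1L]
  v <- pmin(pmax(x[seq_len(n)] + lb, lb), ub)
  list(status = "optimal", solution = v, objective = sum(obj * v))
}
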