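# Brute-force LP oracle: enumerate all basic solutions of
#   max c'v  s.t.  A v = 0,  lb <= v <= ub
# by choosing every basis of size nrow(A) and every lb/ub assignment of
# the non-basic variables.  Exact for small networks; independent of the
# simplex implementation it checks.
brute_force_lp <- function(obj, A, lb, ub) {
  # drop linearly dependent rows (b = 0, so consistency is automatic);
  # otherwise no nonsingular basis exists and vertices are missed
  r <- qr(A)$rank
  if (r < nrow(A)) A <- A[qr(t(A))$pivot[seq_len(r)], , drop = FALSE]
  m <- nrow(A); n <- ncol(A)
  best <- -Inf
  feasible <- FALSE
  combs <- utils::combn(n, m)
  for (ci in seq_len(ncol(combs))) {
    B <- combs[, ci]
    AB <- A[, B, drop = FALSE]
    if (abs(det(AB)) < 1e-10) next
    N <- setdiff(seq_len(n), B)
    for (mask in 0:(2^length(N) - 1)) {
      xN <- numeric(length(N))
      for (k in seq_along(N))
        xN[k] <- if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) > 0) ub[N[k]] else lb[N[k]]
      rhs <- -A[, N, drop = FALSE] %*% xN
      xB <- tryCatch(solve(AB, rhs), error = function(e) NULL)
      if (is.null(xB)) next
      v <- numeric(n); v[B] <- xB; v[N] <- xN
      if (all(v >= lb - 1e-8) && all(v <= ub + 1e-8)) {
        feasible <- TRUE
        best <- max(best, sum(obj * v))
      }
    }
  }
  list(feasible = feasible, objective = if (feasible) best else NA_real_)
}

# random small flux network: m metabolites, n reactions, sparse integer
# stoichiometry, some exchange columns so non-trivial flux is possible
random_small_network <- function(seed, n = 6, m = 3) {
  set.seed(seed)
  repeat {
    A <- matrix(sample(c(-1, 0, 0, 1), m * n, replace = TRUE), m, n)
    if (all(colSums(abs(A)) > 0) && all(rowSums(abs(A)) > 0)) break
  }
  rev <- stats::runif(n) < 0.4
  lb <- ifelse(rev, -stats::runif(n, 0.5, 3), 0)
  ub <- stats::runif(n, 0.5, 3)
  obj <- stats::rnorm(n)
  list(A = A, lb = lb, ub = ub, obj = obj)
}
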