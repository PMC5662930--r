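# Internal segment-cost machinery shared by the heteroscedastic piecewise
# linear family and the Gaussian change-in-the-variance family.
#
# A segment [u, v] is scored by its Gaussian log-likelihood with maximum-
# likelihood plug-in parameters (variance = RSS/n, floored). All feasible
# (u, v) costs are precomputed from running sums of p, p^2, x, x^2 and p*x,
# so dynamic programming over J segments runs in O(J * T^2).

.lse <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# Gaussian segment log-likelihood with a variance floor. Equals
# -(n/2) * (log(2*pi*RSS/n) + 1) whenever RSS/n is above the floor.
.gauss_ll <- function(rss, n, var_floor) {
  s2 <- pmax(rss / n, var_floor)
  -n / 2 * log(2 * pi * s2) - rss / (2 * s2)
}

# Cost table for the piecewise linear model: per-segment OLS of cell length
# on position.
.linear_costs <- function(profile, min_len = 4L, var_floor = 1e-6) {
  p <- profile$positions
  x <- profile$lengths
  T <- length(x)
  min_len <- as.integer(min_len)
  if (min_len < 2L) stop("`min_len` must be at least 2")
  # center globally before accumulating: OLS slopes and RSS are
  # shift-invariant and the running sums lose far less precision
  pg <- p - mean(p)
  xg <- x - mean(x)
  cp <- c(0, cumsum(pg));   cp2 <- c(0, cumsum(pg^2))
  cx <- c(0, cumsum(xg));   cx2 <- c(0, cumsum(xg^2))
  cpx <- c(0, cumsum(pg * xg))
  cost <- matrix(-Inf, T, T)
  for (u in seq_len(T)) {
    if (u + min_len - 1L > T) break
    v <- seq.int(u + min_len - 1L, T)
    n <- v - u + 1
    sp <- cp[v + 1] - cp[u];   sp2 <- cp2[v + 1] - cp2[u]
    sx <- cx[v + 1] - cx[u];   sx2 <- cx2[v + 1] - cx2[u]
    spx <- cpx[v + 1] - cpx[u]
    sxx_p <- sp2 - sp^2 / n
    sxx_x <- sx2 - sx^2 / n
    sxy <- spx - sp * sx / n
    # degenerate position spread: slope undefined, fall back to mean-only RSS
    rss <- ifelse(sxx_p > 1e-12, sxx_x - sxy^2 / sxx_p, sxx_x)
    rss <- pmax(rss, 0)
    # near the variance floor, running-sum cancellation noise is amplified
    # by 1/var_floor in the likelihood: recompute those segments exactly
    redo <- which(rss < 4 * n * var_floor)
    for (k in redo) {
      vv <- v[k]
      pp <- p[u:vv] - mean(p[u:vv])
      xx <- x[u:vv] - mean(x[u:vv])
      sp_k <- sum(pp^2)
      sx_k <- sum(xx^2)
      rss[k] <- if (sp_k > 1e-12) max(sx_k - sum(pp * xx)^2 / sp_k, 0)
                else sx_k
      if (rss[k] < 1e-12 * max(sx_k, 1)) rss[k] <- 0
    }
    cost[u, v] <- .gauss_ll(rss, n, var_floor)
  }
  structure(list(family = "linear", cost = cost, min_len = min_len, T = T,
                 positions = p, values = x, var_floor = var_floor,
                 profile = profile),
            class = "seg_costs")
}

# Cost table for the change-in-variance model: global mean alpha, per-segment
# variance of deviations from alpha.
.variance_costs <- function(series, min_len = 4L, var_floor = 1e-6,
                            positions = NULL, alpha = NULL) {
  x <- as.numeric(series)
  T <- length(x)
  min_len <- as.integer(min_len)
  if (min_len < 2L) stop("`min_len` must be at least 2")
  if (is.null(alpha)) alpha <- mean(x)
  d <- x - alpha
  cd2 <- c(0, cumsum(d^2))
  cost <- matrix(-Inf, T, T)
  for (u in seq_len(T)) {
    if (u + min_len - 1L > T) break
    v <- seq.int(u + min_len - 1L, T)
    n <- v - u + 1
    rss <- pmax(cd2[v + 1] - cd2[u], 0)
    redo <- which(rss < 4 * n * var_floor)
    for (k in redo) rss[k] <- sum(d[u:v[k]]^2)
    cost[u, v] <- .gauss_ll(rss, n, var_floor)
  }
  structure(list(family = "variance", cost = cost, min_len = min_len, T = T,
                 positions = positions, values = x, var_floor = var_floor,
                 alpha = alpha),
            class = "seg_costs")
}

.check_feasible <- function(costs, J) {
  if (J < 1L) stop("`J` must be at least 1")
  if (J * costs$min_len > costs$T)
    stop("infeasible segmentation: J * min_len = ", J * costs$min_len,
         " exceeds T = ", costs$T)
}

# Forward recursion. F[j, t] aggregates over segmentations of cells 1..t into
# exactly j segments (cell t ends segment j); `op` = "max" (Viterbi) or
# "sum" (log-sum-exp, for evidence and posteriors).
.dp_forward <- function(costs, J, op = c("max", "sum")) {
  op <- match.arg(op)
  T <- costs$T; ml <- costs$min_len; cost <- costs$cost
  F <- matrix(-Inf, J, T)
  F[1, ] <- cost[1, ]
  if (J >= 2) for (j in 2:J) {
    tmin <- j * ml
    if (tmin > T) break
    for (t in seq.int(tmin, T)) {
      s <- seq.int((j - 1) * ml + 1L, t - ml + 1L)
      val <- F[j - 1, s - 1] + cost[s, t]
      F[j, t] <- if (op == "max") max(val) else .lse(val)
    }
  }
  F
}

# Backward recursion. B[j, t] aggregates over segmentations of cells t..T
# into exactly j segments (cell t starts the first of them).
.dp_backward <- function(costs, J, op = c("max", "sum")) {
  op <- match.arg(op)
  T <- costs$T; ml <- costs$min_len; cost <- costs$cost
  B <- matrix(-Inf, J, T)
  B[1, ] <- cost[, T]
  if (J >= 2) for (j in 2:J) {
    tmax <- T - j * ml + 1L
    if (tmax < 1L) break
    for (t in seq.int(1L, tmax)) {
      e <- seq.int(t + ml - 1L, T - (j - 1) * ml)
      val <- cost[t, e] + B[j - 1, e + 1]
      B[j, t] <- if (op == "max") max(val) else .lse(val)
    }
  }
  B
}

# Lexicographically-smallest optimal change-point vector, reconstructed from
# the front so that near-ties (within 1e-9 relative) break toward the
# rootward candidate.
.optimal_cps <- function(costs, J) {
  .check_feasible(costs, J)
  T <- costs$T; ml <- costs$min_len; cost <- costs$cost
  if (J == 1L) return(integer(0))
  Bmax <- .dp_backward(costs, J, "max")
  cps <- integer(0)
  prev <- 1L
  acc <- 0
  for (j in seq_len(J - 1L)) {
    t_cand <- seq.int(prev + ml, T - (J - j) * ml + 1L)
    sc <- acc + cost[prev, t_cand - 1L] + Bmax[J - j, t_cand]
    m <- max(sc)
    tol <- 1e-9 * max(1, abs(m))
    t <- t_cand[which(sc >= m - tol)[1]]
    cps <- c(cps, t)
    acc <- acc + cost[prev, t - 1L]
    prev <- t
  }
  cps
}

# N-best segmentations: generalized Viterbi keeping, per (j, t) state, the
# top-N partial scores together with their full change-point vectors. Exact
# score ties are broken by the lexicographically smaller change-point vector.
.topn_cps <- function(costs, J, N) {
  .check_feasible(costs, J)
  T <- costs$T; ml <- costs$min_len; cost <- costs$cost
  if (J == 1L)
    return(list(scores = cost[1, T], cps = matrix(0L, 1, 0)))
  states <- vector("list", T)
  for (t in seq.int(ml, T))
    states[[t]] <- list(scores = cost[1, t], cps = matrix(0L, 1, 0))
  for (j in 2:J) {
    new_states <- vector("list", T)
    tmin <- j * ml
    t_top <- if (j == J) T else T - (J - j) * ml
    if (tmin <= t_top) for (t in seq.int(tmin, t_top)) {
      if (j == J && t != T) next
      s_cand <- seq.int((j - 1) * ml + 1L, t - ml + 1L)
      sc_list <- vector("list", length(s_cand))
      cp_list <- vector("list", length(s_cand))
      for (k in seq_along(s_cand)) {
        s <- s_cand[k]
        st <- states[[s - 1L]]
        if (is.null(st)) next
        sc_list[[k]] <- st$scores + cost[s, t]
        cp_list[[k]] <- cbind(st$cps, s, deparse.level = 0)
      }
      sc <- unlist(sc_list)
      if (is.null(sc)) next
      cpm <- do.call(rbind, cp_list)
      keep <- is.finite(sc)
      if (!any(keep)) next
      sc <- sc[keep]; cpm <- cpm[keep, , drop = FALSE]
      ord_args <- c(list(-sc), lapply(seq_len(ncol(cpm)), function(i) cpm[, i]))
      o <- do.call(order, ord_args)
      o <- o[seq_len(min(N, length(o)))]
      new_states[[t]] <- list(scores = sc[o], cps = cpm[o, , drop = FALSE])
    }
    states <- new_states
  }
  st <- states[[T]]
  if (is.null(st)) stop("no feasible segmentation found")
  st
}
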