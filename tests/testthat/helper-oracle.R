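# Brute-force oracles, independent of the package's dynamic-programming
# path: segmentations are enumerated explicitly and per-segment fits use
# stats::lm().

enum_segmentations <- function(T, J, min_len) {
  if (J == 1) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, prev, j) {
    if (j > J - 1) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (t in seq.int(prev + min_len, T - (J - j) * min_len + 1))
      rec(c(prefix, t), t, j + 1)
  }
  rec(integer(0), 1L, 1L)
  out
}

oracle_loglik <- function(pos, len, cps, var_floor = 1e-6) {
  st <- c(1L, cps)
  en <- c(cps - 1L, length(len))
  sum(mapply(function(u, v) {
    f <- stats::lm(x ~ p, data.frame(p = pos[u:v], x = len[u:v]))
    rss <- sum(stats::resid(f)^2)
    n <- v - u + 1
    s2 <- max(rss / n, var_floor)
    -n / 2 * log(2 * pi * s2) - rss / (2 * s2)
  }, st, en))
}

oracle_loglik_variance <- function(x, cps, var_floor = 1e-6) {
  alpha <- mean(x)
  st <- c(1L, cps)
  en <- c(cps - 1L, length(x))
  sum(mapply(function(u, v) {
    rss <- sum((x[u:v] - alpha)^2)
    n <- v - u + 1
    s2 <- max(rss / n, var_floor)
    -n / 2 * log(2 * pi * s2) - rss / (2 * s2)
  }, st, en))
}

log_sum_exp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

# All posterior quantities by enumeration. Returns log-likelihoods sorted as
# enumerated, evidence, posterior weights, occupancy and max-type profiles,
# and per-limit change-point distributions.
oracle_posteriors <- function(pos, len, J, min_len, var_floor = 1e-6,
                              loglik_fun = oracle_loglik) {
  T <- length(len)
  segs <- enum_segmentations(T, J, min_len)
  lls <- vapply(segs, function(cp) loglik_fun(pos, len, cp, var_floor),
                numeric(1))
  ev <- log_sum_exp(lls)
  w <- exp(lls - ev)
  occ <- matrix(0, T, J)
  prof <- matrix(0, T, J)
  cps <- lapply(seq_len(max(J - 1, 0)), function(j) numeric(T))
  for (k in seq_along(segs)) {
    b <- c(1L, segs[[k]], T + 1L)
    for (j in seq_len(J)) {
      idx <- b[j]:(b[j + 1] - 1L)
      occ[idx, j] <- occ[idx, j] + w[k]
      prof[idx, j] <- pmax(prof[idx, j], w[k])
    }
    for (j in seq_len(max(J - 1, 0)))
      cps[[j]][segs[[k]][j]] <- cps[[j]][segs[[k]][j]] + w[k]
  }
  list(segs = segs, lls = lls, evidence = ev, weights = w,
       occupancy = occ, profiles = prof, changepoints = cps)
}

# variance-family wrapper with the oracle signature
oracle_loglik_var_wrap <- function(pos, len, cps, var_floor = 1e-6) {
  oracle_loglik_variance(len, cps, var_floor)
}

random_profile <- function(T, scale = 100) {
  cell_profile(sort(runif(T, 0, scale)), abs(rnorm(T, 10, 4)) + 0.5)
}
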