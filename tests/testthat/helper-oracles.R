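# Independent brute-force / closed-form oracles used to validate the
# package's statistical primitives. Deliberately written loop-by-loop,
# sharing no code with the implementation.

oracle_tmm <- function(counts, logratio_trim = 0.3, abundance_trim = 0.05) {
  counts <- as.matrix(counts)
  lib <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) lib[j] <- sum(counts[, j])
  uq <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    uq[j] <- unname(quantile(counts[, j], 0.75)) / lib[j]
  }
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (j == ref) { f[j] <- 1; next }
    M <- c(); A <- c(); W <- c()
    for (b in seq_len(nrow(counts))) {
      o <- counts[b, j]; r <- counts[b, ref]
      if (o > 0 && r > 0) {
        m <- log2((o / lib[j]) / (r / lib[ref]))
        a <- 0.5 * log2((o / lib[j]) * (r / lib[ref]))
        if (is.finite(m) && is.finite(a)) {
          M <- c(M, m); A <- c(A, a)
          W <- c(W, (lib[j] - o) / (lib[j] * o) +
                   (lib[ref] - r) / (lib[ref] * r))
        }
      }
    }
    if (length(M) == 0 || max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * abundance_trim) + 1; hi_a <- n + 1 - lo_a
    rM <- rank(M); rA <- rank(A)
    num <- 0; den <- 0; kept <- 0
    for (i in seq_len(n)) {
      if (rM[i] >= lo_m && rM[i] <= hi_m && rA[i] >= lo_a && rA[i] <= hi_a) {
        num <- num + M[i] / W[i]; den <- den + 1 / W[i]; kept <- kept + 1
      }
    }
    f[j] <- if (kept == 0) 1 else 2^(num / den)
  }
  g <- exp(mean(log(f)))
  f / g
}

oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- numeric(m)
  cur <- 1
  for (i in m:1) {
    cur <- min(cur, m * p[o[i]] / i)
    adj[o[i]] <- cur
  }
  adj
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(xs, ys) {
    u <- 0
    for (a in xs) for (b in ys) u <- u + (a > b) + 0.5 * (a == b)
    u
  }
  obs <- u_of(x, y)
  combos <- combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) {
    u_of(pooled[idx], pooled[-idx])
  })
  mid <- n1 * n2 / 2
  p <- if (obs > mid) {
    2 * mean(us >= obs)
  } else {
    2 * mean(us <= obs)
  }
  list(U = obs, p = min(1, p))
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  mx <- mean(rx); my <- mean(ry)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (rx[i] - mx) * (ry[i] - my)
    dx <- dx + (rx[i] - mx)^2
    dy <- dy + (ry[i] - my)^2
  }
  rho <- num / sqrt(dx * dy)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tt), n - 2))
}

oracle_two_prop_z <- function(k1, n1, k2, n2) {
  ph <- (k1 + k2) / (n1 + n2)
  (k1 / n1 - k2 / n2) / sqrt(ph * (1 - ph) * (1 / n1 + 1 / n2))
}

# Log-rank O/E/variance by direct tabulation over distinct event times.
oracle_logrank <- function(times, events, groups) {
  groups <- as.integer(factor(groups))
  evt_times <- sort(unique(times[events == 1]))
  O1 <- 0; E1 <- 0; V <- 0; O2 <- 0; E2 <- 0
  for (t in evt_times) {
    at1 <- sum(times >= t & groups == 1)
    at2 <- sum(times >= t & groups == 2)
    d1 <- sum(times == t & events == 1 & groups == 1)
    d2 <- sum(times == t & events == 1 & groups == 2)
    d <- d1 + d2; n <- at1 + at2
    O1 <- O1 + d1; O2 <- O2 + d2
    E1 <- E1 + d * at1 / n
    E2 <- E2 + d * at2 / n
    if (n > 1) {
      V <- V + d * (at1 / n) * (at2 / n) * (n - d) / (n - 1)
    }
  }
  chisq <- (O1 - E1)^2 / V
  list(O = c(O1, O2), E = c(E1, E2), V = V, chisq = chisq,
       p = pchisq(chisq, 1, lower.tail = FALSE),
       hr = (O1 / E1) / (O2 / E2))
}

# Exact Poisson-limit split test: doubled upper binomial tail of y1 out of
# y1 + y2 with success probability 1 / (1 + n_rep).
oracle_poisson_split <- function(y1, y2, n_rep) {
  t <- y1 + y2
  if (t == 0) return(1)
  p_up <- 0
  for (k in y1:t) p_up <- p_up + dbinom(k, t, 1 / (1 + n_rep))
  min(1, 2 * p_up)
}

# Independent origin/engraftment reference over a named detection vector
# (first-appearance bookkeeping written as explicit index arithmetic).
oracle_kinetics <- function(det) {
  tps <- c("preACT", "TIL", "post1", "post4", "post12", "post24", "post48")
  d <- rep(FALSE, 7); names(d) <- tps
  d[names(det)] <- det
  hits <- which(d)
  if (length(hits) == 0) {
    return(list(category = NA_character_, engrafted = FALSE,
                persisting = FALSE))
  }
  first <- min(hits)
  category <- if (d[1] && d[2]) "pre_TIL"
    else if (d[1]) "preACT_only"
    else if (first == 2) "TIL"
    else paste0("novel_", tps[first])
  n_post <- sum(d[3:7])
  list(category = category,
       engrafted = d[2] && n_post >= 1,
       persisting = n_post >= 2)
}
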