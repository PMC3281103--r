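# Brute-force dip oracle: linear program over unimodal CDFs with knots at the
# unique data values (convex branch, optional atom at the mode, concave
# branch), minimising the sup-distance to the empirical CDF. Exact for the
# tiny sample sizes it is used at (n <= 5); independent of the
# hull-construction path used by dip_statistic().
dip_oracle <- function(x) {
  x <- sort(x)
  ux <- unique(x); m <- length(ux); n <- length(x)
  cnt <- tabulate(match(x, ux), m)
  A <- cumsum(cnt) / n; B <- A - cnt / n
  if (m == 1) return(0)
  d <- diff(ux)
  best <- Inf
  for (j in 1:m) {
    nv <- m + 2; ih <- m + 1; it <- m + 2
    obj <- numeric(nv); obj[it] <- 1
    A1 <- NULL; b1 <- NULL # <= rows
    A2 <- NULL; b2 <- NULL # >= rows
    for (i in 1:m) {
      r <- numeric(nv); r[i] <- 1; r[it] <- -1
      A1 <- rbind(A1, r); b1 <- c(b1, B[i])                      # g_i - t <= B_i
      r <- numeric(nv); r[i] <- 1; r[it] <- 1
      A2 <- rbind(A2, r); b2 <- c(b2, if (i == j) B[i] else A[i]) # g_i + t >= A_i
    }
    r <- numeric(nv); r[ih] <- 1; r[it] <- -1; A1 <- rbind(A1, r); b1 <- c(b1, A[j])
    r <- numeric(nv); r[ih] <- 1; r[it] <- 1; A2 <- rbind(A2, r); b2 <- c(b2, A[j])
    for (i in seq_len(m - 1)) { # monotone, with the jump g_j <= h at the mode
      r <- numeric(nv)
      if (i == j) { r[ih] <- 1; r[i + 1] <- -1 } else { r[i] <- 1; r[i + 1] <- -1 }
      A1 <- rbind(A1, r); b1 <- c(b1, 0)
    }
    r <- numeric(nv); r[j] <- 1; r[ih] <- -1; A1 <- rbind(A1, r); b1 <- c(b1, 0)
    if (j >= 3) for (i in 2:(j - 1)) { # convexity left of the mode
      r <- numeric(nv); r[i + 1] <- d[i - 1]; r[i] <- -(d[i - 1] + d[i]); r[i - 1] <- d[i]
      A2 <- rbind(A2, r); b2 <- c(b2, 0)
    }
    if (j + 1 <= m - 1) for (i in (j + 1):(m - 1)) { # concavity right of the mode
      r <- numeric(nv); r[i + 1] <- d[i - 1]; r[i] <- -(d[i - 1] + d[i])
      if (i - 1 == j) r[ih] <- d[i] else r[i - 1] <- d[i]
      A1 <- rbind(A1, r); b1 <- c(b1, 0)
    }
    res <- suppressWarnings(
      boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2, maxi = FALSE)
    )
    if (res$solved == 1) best <- min(best, res$value)
  }
  best
}

# sigmoidal fraction curve used across tests, pinned to s = 0 / 1 at the ends
make_sigmoid_curve <- function(pd_lo = 25, pd_hi = 47, mid = 36, k = 0.45,
                               half_band = 0.02) {
  pd <- seq(pd_lo, pd_hi, by = 1)
  s <- stats::plogis(k * (pd - mid))
  s <- (s - s[1]) / (s[length(s)] - s[1])
  fraction_curve(tibble::tibble(
    pd = pd, s_mean = s,
    s_lower = pmax(0, s - half_band), s_upper = pmin(1, s + half_band)
  ))
}
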