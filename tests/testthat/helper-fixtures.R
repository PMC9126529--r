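# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures ship with the package.

# filled disc mask of radius r centred in an n x n matrix
disc_mask <- function(r, n = 2 * r + 21, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  y <- matrix(seq_len(n), n, n)
  x <- t(y)
  (y - cy)^2 + (x - cx)^2 <= r^2
}

# axis-aligned filled ellipse mask (semi-axes ay, ax)
ellipse_mask <- function(ay, ax, n = 2 * max(ay, ax) + 21) {
  c0 <- (n + 1) / 2
  y <- matrix(seq_len(n), n, n)
  x <- t(y)
  ((y - c0) / ay)^2 + ((x - c0) / ax)^2 <= 1
}

rot90_mask <- function(m) t(m[nrow(m):1, , drop = FALSE])

# small sim_params for fast image-mode work (overrides win)
tiny_params <- function(...) {
  args <- utils::modifyList(
    list(n_patients = 4, tile_px = 192, tiles_per_patient = 2,
         blasts_per_tile_range = c(3, 5),
         other_wbc_per_tile_range = c(3, 6), rbc_per_tile = 6),
    list(...))
  do.call(sim_params, args)
}

# closed-form P(event) oracle for the exponential + uniform-censoring
# model: P(T <= U) = 1 - (1 - exp(-c r)) / (c r) for rate r, horizon c,
# averaged over the uniform h law by quadrature
oracle_event_fraction <- function(beta, baseline, horizon, h_range) {
  f <- function(h) {
    r <- baseline * exp(beta * h)
    1 - (1 - exp(-horizon * r)) / (horizon * r)
  }
  stats::integrate(function(h) vapply(h, f, numeric(1)),
                   h_range[1], h_range[2])$value / diff(h_range)
}

# independent brute-force GLCM oracle: double loop over all pixel pairs
oracle_glcm <- function(gray, mask, n_levels, offsets, symmetric = TRUE) {
  v <- gray[mask]
  lo <- min(v); hi <- max(v)
  q <- matrix(0L, nrow(gray), ncol(gray))
  if (hi > lo)
    q[mask] <- pmin(as.integer(floor((gray[mask] - lo) / (hi - lo) * n_levels)),
                    n_levels - 1L)
  counts <- matrix(0, n_levels, n_levels)
  for (off in offsets)
    for (i in seq_len(nrow(gray)))
      for (j in seq_len(ncol(gray))) {
        i2 <- i + off[1]; j2 <- j + off[2]
        if (i2 < 1 || i2 > nrow(gray) || j2 < 1 || j2 > ncol(gray)) next
        if (!mask[i, j] || !mask[i2, j2]) next
        a <- q[i, j] + 1L; b <- q[i2, j2] + 1L
        counts[a, b] <- counts[a, b] + 1
        if (symmetric) counts[b, a] <- counts[b, a] + 1
      }
  if (sum(counts) == 0) counts else counts / sum(counts)
}

# brute-force Harrell C over all ordered pairs
oracle_harrell_c <- function(scores, times, events) {
  conc <- ties <- comp <- 0
  n <- length(scores)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (events[i] != 1 || times[i] >= times[j]) next
    comp <- comp + 1
    if (scores[i] > scores[j]) conc <- conc + 1
    else if (scores[i] == scores[j]) ties <- ties + 0.5
  }
  (conc + ties) / comp
}

# brute-force two-sample log-rank: explicit risk table per event time
oracle_logrank <- function(times, events, groups) {
  g <- as.integer(as.factor(groups))   # 1 or 2
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & g == 1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + d1 - e1
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# brute-force trapezoid-free AUC: Mann-Whitney pair count with tie credit
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
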