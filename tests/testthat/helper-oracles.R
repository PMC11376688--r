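# Independent oracles used across the suite. Each one deliberately takes a
# different algorithmic route than the package implementation it checks.

# Signed torsion via the projection ("praxeolitic") formula: project the
# outer bonds onto the plane normal to the central bond and take atan2.
dihedral_oracle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum((c(b1[2] * v[3] - b1[3] * v[2],
              b1[3] * v[1] - b1[1] * v[3],
              b1[1] * v[2] - b1[2] * v[1])) * w)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  rbind(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
        c(2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b)),
        c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2))
}

# Hand product-limit table: S(t) = prod over event times <= t of
# (1 - d_i / n_i), censored records at risk until their censor time.
km_oracle <- function(time, event, t_eval) {
  ev_times <- sort(unique(time[event]))
  vapply(t_eval, function(t) {
    s <- 1
    for (te in ev_times[ev_times <= t]) {
      n_risk <- sum(time >= te)
      d <- sum(time == te & event)
      s <- s * (1 - d / n_risk)
    }
    s
  }, numeric(1))
}

# Exhaustive grid maximum of the uncensored two-component mixture
# log-likelihood over (tau1, tau2, a1) at fixed resolution.
grid_loglik_max <- function(t_obs, tau1_grid, tau2_grid, a_grid) {
  d2 <- outer(1 / tau2_grid, t_obs, function(r, t) r * exp(-t * r))
  best <- -Inf
  for (tau1 in tau1_grid) {
    d1 <- exp(-t_obs / tau1) / tau1
    for (a in a_grid) {
      dens <- a * matrix(d1, nrow = length(tau2_grid), ncol = length(t_obs),
                         byrow = TRUE) + (1 - a) * d2
      ll <- rowSums(log(dens))
      m <- max(ll)
      if (m > best) best <- m
    }
  }
  best
}

# Leading eigenpairs of a covariance matrix by power iteration + deflation.
power_iteration_eigen <- function(C, n_vec = 2, iter = 5000) {
  vals <- numeric(n_vec)
  vecs <- matrix(0, nrow(C), n_vec)
  M <- C
  for (k in seq_len(n_vec)) {
    v <- rep(1, nrow(C)) / sqrt(nrow(C))
    for (i in seq_len(iter)) {
      v2 <- M %*% v
      v2 <- v2 / sqrt(sum(v2^2))
      if (max(abs(v2 - v)) < 1e-14) { v <- v2; break }
      v <- v2
    }
    lam <- drop(t(v) %*% M %*% v)
    vals[k] <- lam
    vecs[, k] <- v
    M <- M - lam * (v %*% t(v))
  }
  list(values = vals, vectors = vecs)
}

# Brute-force double loop over donor/acceptor pairs.
brute_hbonds <- function(frame, donors, acceptors, cutoff = 3.5) {
  out <- list()
  for (d in donors) {
    pd <- unlist(frame[frame$label == d, c("x", "y", "z")])
    for (a in acceptors) {
      if (d == a) next
      pa <- unlist(frame[frame$label == a, c("x", "y", "z")])
      dist <- sqrt(sum((pd - pa)^2))
      if (dist <= cutoff) out[[length(out) + 1]] <- c(d, a, dist)
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor = character(), acceptor = character(),
                      distance = numeric()))
  }
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("donor", "acceptor", "distance")
  df$distance <- as.numeric(df$distance)
  df[order(df$distance), ]
}

partition_wss <- function(x, labels) {
  sum(vapply(unique(labels), function(l) {
    xs <- x[labels == l, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }, numeric(1)))
}

# Minimum within-cluster sum of squares over every bipartition of n points.
min_bipartition_wss <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(mask))[1:n]
    best <- min(best, partition_wss(x, lab))
  }
  best
}

# Closed-form Wilson score interval, written out directly.
wilson_interval <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(center - half, center + half)
}
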