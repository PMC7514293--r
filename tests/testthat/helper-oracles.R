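# Independent brute-force oracles used to cross-check the package's
# vectorized implementations. These deliberately use the most naive
# formulation available (explicit loops, permutation enumeration).

# stack-based 8-connected flood fill; labels in raster order of first pixel
flood_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (mask[r0, c0] && lab[r0, c0] == 0L) {
      cur <- cur + 1L
      stack <- list(c(r0, c0))
      lab[r0, c0] <- cur
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1] + dr; c <- p[2] + dc
          if (r >= 1 && r <= h && c >= 1 && c <= w &&
              mask[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- cur
            stack[[length(stack) + 1]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# double-loop time-averaged-then-ensemble-averaged MSD
brute_msd <- function(trajs, k_max, dt) {
  sums <- numeric(k_max); ntr <- integer(k_max); nobs <- integer(k_max)
  for (tr in trajs) {
    p <- cbind(tr$x_um, tr$y_um)
    n <- nrow(p)
    if (n < 2) next
    for (k in seq_len(min(k_max, n - 1))) {
      acc <- 0
      for (i in seq_len(n - k)) acc <- acc + sum((p[i + k, ] - p[i, ])^2)
      sums[k] <- sums[k] + acc / (n - k)
      ntr[k] <- ntr[k] + 1L
      nobs[k] <- nobs[k] + (n - k)
    }
  }
  keep <- ntr > 0
  list(lag_s = (seq_len(k_max) * dt)[keep],
       msd = (sums / pmax(ntr, 1))[keep], n_obs = nobs[keep])
}

# textbook paired t-test
brute_paired_t <- function(pre, post) {
  d <- post - pre
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), n - 1))
}

# optimal two-frame assignment by permutation enumeration (n <= 6);
# cost = sum of linked distances + max_disp penalty per unlinked point
optimal_assignment_cost <- function(p1, p2, max_disp) {
  n <- nrow(p1)
  stopifnot(nrow(p2) == n, n <= 6)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (pm in perms(seq_len(n))) {
    d <- sqrt(rowSums((p1 - p2[pm, , drop = FALSE])^2))
    cost <- sum(ifelse(d <= max_disp, d, max_disp))
    if (cost < best) best <- cost
  }
  best
}

# greedy linking cost on a two-frame fixture, same cost convention
greedy_assignment_cost <- function(p1, p2, max_disp) {
  det <- tibble::tibble(
    frame = rep(0:1, c(nrow(p1), nrow(p2))),
    x_um = c(p1[, 1], p2[, 1]), y_um = c(p1[, 2], p2[, 2]))
  trajs <- diffent::link(det, max_disp = max_disp, min_len = 1)
  linked <- Filter(function(tr) nrow(tr) == 2, trajs)
  cost <- sum(vapply(linked, function(tr) {
    sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  }, numeric(1)))
  cost + max_disp * (nrow(p1) - length(linked))
}

# greedy linked pairs as an index map frame0 -> frame1 (NA if unlinked)
greedy_matching <- function(p1, p2, max_disp) {
  det <- tibble::tibble(
    frame = rep(0:1, c(nrow(p1), nrow(p2))),
    x_um = c(p1[, 1], p2[, 1]), y_um = c(p1[, 2], p2[, 2]))
  trajs <- diffent::link(det, max_disp = max_disp, min_len = 1)
  m <- rep(NA_integer_, nrow(p1))
  for (tr in trajs) {
    if (nrow(tr) == 2) {
      i <- which(p1[, 1] == tr$x_um[1] & p1[, 2] == tr$y_um[1])
      j <- which(p2[, 1] == tr$x_um[2] & p2[, 2] == tr$y_um[2])
      m[i] <- j
    }
  }
  m
}
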