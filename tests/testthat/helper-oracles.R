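# Independent oracles used across the suite. These deliberately use naive
# loop-based formulations, not the package's vectorized code paths.

# sum of singular components idx of a complex matrix, straight from svd()
svd_component_sum <- function(m, idx) {
  s <- svd(m)
  out <- matrix(0i, nrow(m), ncol(m))
  for (i in idx) out <- out + s$d[i] * s$u[, i, drop = FALSE] %*% Conj(t(s$v[, i, drop = FALSE]))
  out
}

# per-pixel time-loop power Doppler
power_doppler_loop <- function(stack) {
  d <- dim(stack$data)
  out <- matrix(0, d[1], d[2])
  for (ix in seq_len(d[1])) for (iz in seq_len(d[2])) {
    acc <- 0
    for (it in seq_len(d[3])) acc <- acc + Mod(stack$data[ix, iz, it])^2
    out[ix, iz] <- acc / d[3]
  }
  out
}

# type-7 percentile by explicit order statistics
percentile_oracle <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# intermeans fixed point by enumeration over split points: find the split of
# the sorted sample whose between-class midpoint falls inside the split gap
intermeans_oracle <- function(x) {
  xs <- sort(unique(x))
  if (length(xs) < 2) return(NA_real_)
  for (k in seq_len(length(xs) - 1)) {
    t_cand <- (mean(x[x <= xs[k]]) + mean(x[x > xs[k]])) / 2
    if (t_cand > xs[k] && t_cand <= xs[k + 1]) return(t_cand)
  }
  NA_real_
}

# breadth-first flood fill, components numbered by smallest linear index
flood_fill_labels <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  nxt <- 0L
  for (v in which(mask)) {
    if (lab[v] > 0L) next
    nxt <- nxt + 1L
    lab[v] <- nxt
    queue <- arrayInd(v, d)
    while (nrow(queue) > 0) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        nb <- cur + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nxt
          queue <- rbind(queue, nb, deparse.level = 0)
        }
      }
    }
  }
  lab
}

# Friedman statistic from definition, with explicit per-row midranks
friedman_oracle <- function(blocks) {
  n <- nrow(blocks); k <- ncol(blocks)
  rk <- matrix(0, n, k)
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      less <- sum(blocks[i, ] < blocks[i, j])
      equal <- sum(blocks[i, ] == blocks[i, j])
      rk[i, j] <- less + (equal + 1) / 2
    }
  }
  rj <- colSums(rk)
  12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
}

# one-way F statistic from sums of squares
anova_f_oracle <- function(samples) {
  all_v <- unlist(samples)
  gm <- mean(all_v)
  ss_b <- sum(vapply(samples, function(s) length(s) * (mean(s) - gm)^2, 1))
  ss_w <- sum(vapply(samples, function(s) sum((s - mean(s))^2), 1))
  k <- length(samples); n <- length(all_v)
  (ss_b / (k - 1)) / (ss_w / (n - k))
}

# a small single-vessel Doppler test scene with ROIs matching the vessel
make_recovery_scene <- function(r, seed, nx = 32, nz = 24, nt = 80) {
  mask <- matrix(FALSE, nx, nz)
  mask[10:12, ] <- TRUE
  truth <- doppler_scene_truth(tissue_rank = r, vessel_mask = mask, seed = seed)
  scene <- gen_doppler_scene(truth, nx = nx, nz = nz, nt = nt)
  list(scene = scene,
       blood = rect_roi(nx, nz, c(11, 12), label = "blood"),
       noise = rect_roi(nx, nz, c(27, 12), label = "noise"))
}

random_complex_matrix <- function(nr, nc) {
  matrix(complex(real = rnorm(nr * nc), imaginary = rnorm(nr * nc)), nr, nc)
}
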