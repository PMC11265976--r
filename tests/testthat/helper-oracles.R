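# Independent straight-line oracles, coded with plain loops so they share no
# code path with the package implementation.

# per-pixel response-map oracle: baseline mean -> dF/F -> mean over peak
# window -> brute-force disc minimum filter per plane -> max over z -> clip
oracle_response_map <- function(arr, baseline = 1:5, peak = 9:14,
                                radius = 2, clip = c(-1, 4)) {
  d <- dim(arr)
  eps <- 1e-6 * max(arr)
  planes <- array(0, d[2:4])
  for (z in seq_len(d[2])) {
    for (y in seq_len(d[3])) {
      for (x in seq_len(d[4])) {
        b <- mean(arr[baseline, z, y, x])
        planes[z, y, x] <- if (b <= eps) 0 else mean((arr[peak, z, y, x] - b) / b)
      }
    }
  }
  filt <- planes
  if (radius > 0) {
    for (z in seq_len(d[2])) {
      for (y in seq_len(d[3])) {
        for (x in seq_len(d[4])) {
          lo <- Inf
          for (dy in -radius:radius) for (dx in -radius:radius) {
            if (dy^2 + dx^2 <= radius^2) {
              yy <- min(max(y + dy, 1), d[3])
              xx <- min(max(x + dx, 1), d[4])
              lo <- min(lo, planes[z, yy, xx])
            }
          }
          filt[z, y, x] <- lo
        }
      }
    }
  }
  out <- matrix(-Inf, d[3], d[4])
  for (z in seq_len(d[2])) out <- pmax(out, filt[z, , ])
  pmin(pmax(out, clip[1]), clip[2])
}

oracle_min_filter <- function(img, radius) {
  out <- img
  for (y in seq_len(nrow(img))) for (x in seq_len(ncol(img))) {
    lo <- Inf
    for (dy in -radius:radius) for (dx in -radius:radius) {
      if (dy^2 + dx^2 <= radius^2) {
        yy <- min(max(y + dy, 1), nrow(img))
        xx <- min(max(x + dx, 1), ncol(img))
        lo <- min(lo, img[yy, xx])
      }
    }
    out[y, x] <- lo
  }
  out
}

# quadratic OLS via explicit normal equations
oracle_quadratic <- function(t, y) {
  X <- cbind(t^2, t, 1)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(coef = as.numeric(beta), ss = sum((y - X %*% beta)^2))
}

# registration residual relative to simulator ground truth, after removing
# the unidentifiable constant offset (the registration reference is built
# from baseline frames that themselves carry motion)
max_registration_residual <- function(shifts, truth_shifts) {
  est <- aggregate(cbind(dy, dx) ~ frame, data = shifts, FUN = mean)
  est <- est[order(est$frame), ]
  ry <- est$dy + truth_shifts$dy
  rx <- est$dx + truth_shifts$dx
  max(abs(c(ry - mean(ry), rx - mean(rx))))
}

random_movie <- function(dims, lo = 50, hi = 150) {
  array(runif(prod(dims), lo, hi), dim = dims)
}
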