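# Independent oracles used across the suite. Each deliberately uses a
# different algorithm from the implementation it checks.

# exhaustive-scan FWHM median: baseline from edge medians, half-max by direct
# comparison, median over the raw samples at or above half-max between the
# first and last such sample
oracle_fwhm_median <- function(v) {
  n <- length(v)
  ne <- max(1, floor(0.1 * n))
  base <- min(median(v[1:ne]), median(v[(n - ne + 1):n]))
  vc <- v - base
  half <- max(vc) / 2
  idx <- which(vc >= half)
  median(v[min(idx):max(idx)])
}

# label-propagation connected components (4-connectivity): iterate "take the
# min label among self and foreground neighbours" to a fixed point
oracle_components <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  lab[bin] <- seq_len(sum(bin))
  repeat {
    changed <- FALSE
    for (r in seq_len(H)) for (cc in seq_len(W)) {
      if (!bin[r, cc]) next
      best <- lab[r, cc]
      if (r > 1 && bin[r - 1, cc]) best <- min(best, lab[r - 1, cc])
      if (r < H && bin[r + 1, cc]) best <- min(best, lab[r + 1, cc])
      if (cc > 1 && bin[r, cc - 1]) best <- min(best, lab[r, cc - 1])
      if (cc < W && bin[r, cc + 1]) best <- min(best, lab[r, cc + 1])
      if (best < lab[r, cc]) { lab[r, cc] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  unname(lapply(split(which(lab > 0), lab[lab > 0]), sort))
}

# brute-force one-way within-subject ANOVA from raw sums of squares
# m: subjects x conditions matrix
oracle_rm_anova_F <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ss_cond <- n * sum((colMeans(m) - gm)^2)
  ss_subj <- k * sum((rowMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  F <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  list(F = F, df1 = k - 1, df2 = (n - 1) * (k - 1),
       eta_p = ss_cond / (ss_cond + ss_err))
}

# pooled two-sample t from the textbook formula
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Liang-Barsky: does the open segment (x0,y0)-(x1,y1) intersect the closed
# axis-aligned rectangle [xl,xh] x [yl,yh] with positive length (or lie
# inside it)?
oracle_segment_hits_rect <- function(x0, y0, x1, y1, xl, xh, yl, yh) {
  dx <- x1 - x0; dy <- y1 - y0
  t0 <- 0; t1 <- 1
  for (e in list(c(-dx, x0 - xl), c(dx, xh - x0),
                 c(-dy, y0 - yl), c(dy, yh - y0))) {
    p <- e[1]; q <- e[2]
    if (p == 0) { if (q < 0) return(FALSE) } else {
      r <- q / p
      if (p < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
      if (t0 > t1) return(FALSE)
    }
  }
  TRUE
}

# all 0-based cell ids a segment crosses, by testing every cell
oracle_raster_cells <- function(x0, y0, x1, y1, cell, nx, ny) {
  ids <- integer(0)
  for (cy in 0:(ny - 1)) for (cx in 0:(nx - 1)) {
    if (oracle_segment_hits_rect(x0, y0, x1, y1,
                                 cx * cell, (cx + 1) * cell,
                                 cy * cell, (cy + 1) * cell))
      ids <- c(ids, cx + cy * nx)
  }
  ids
}

# helper: a symmetric triangular force pulse on a zero baseline
triangle_profile <- function(peak = 8, n = 101, rate = 50) {
  half <- (n - 1) / 2
  v <- peak * (1 - abs(seq(-half, half)) / half)
  timeseries(v, rate = rate, units = "force-au")
}

# helper: pure sinusoid timeseries
tone <- function(freq, rate = 2048, dur = 2, amp = 1, phase = 0) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  timeseries(amp * sin(2 * pi * freq * t + phase), rate = rate)
}

rms <- function(x) sqrt(mean(x^2))
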