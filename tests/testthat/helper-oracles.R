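# Independent oracles used to check the package's fast implementations.
# These are deliberately naive (scalar loops, exhaustive enumeration) and
# share no code with the implementations they verify.

# Pearson correlation by explicit scalar accumulation loops.
pearson_loop <- function(a, b, region = NULL) {
  if (is.null(region)) region <- matrix(TRUE, nrow(a), ncol(a))
  n <- 0; sa <- 0; sb <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (region[i, j]) { n <- n + 1; sa <- sa + a[i, j]; sb <- sb + b[i, j] }
  }
  ma <- sa / n; mb <- sb / n
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (region[i, j]) {
      num <- num + (a[i, j] - ma) * (b[i, j] - mb)
      da <- da + (a[i, j] - ma)^2
      db <- db + (b[i, j] - mb)^2
    }
  }
  num / sqrt(da * db)
}

# Longest >= threshold run by exhaustive enumeration of all contiguous
# intervals; earliest of the equally longest wins. Returns 0-based (start, end).
longest_run_oracle <- function(curve, fraction) {
  thr <- fraction * max(curve)
  best <- NULL
  for (s in seq_along(curve)) for (e in s:length(curve)) {
    if (all(curve[s:e] >= thr)) {
      if (is.null(best) || (e - s) > (best[2] - best[1])) best <- c(s, e)
    }
  }
  best - 1L
}

# Random structured masks: unions of a few rectangles and disks plus salt
# pixels, exercising holes, saddles and border contact.
random_blob_mask <- function(nr, nc, n_blobs = 3L, salt = 0.01) {
  m <- matrix(FALSE, nr, nc)
  for (k in seq_len(n_blobs)) {
    if (runif(1) < 0.5) {
      r0 <- sample(nr, 1); c0 <- sample(nc, 1)
      r1 <- min(nr, r0 + sample(2:8, 1)); c1 <- min(nc, c0 + sample(2:8, 1))
      m[r0:r1, c0:c1] <- TRUE
    } else {
      cr <- runif(1, 1, nr); cc <- runif(1, 1, nc); rad <- runif(1, 1.5, 5)
      for (i in seq_len(nr)) for (j in seq_len(nc))
        if ((i - cr)^2 + (j - cc)^2 <= rad^2) m[i, j] <- TRUE
    }
  }
  m | matrix(runif(nr * nc) < salt, nr, nc)
}

# Small, fast phantom for module-level tests.
small_phantom_config <- function(seed = 11L, ...) {
  phantom_config(n_frames = 30L, period_frames = 8L,
                 bolus_window = contrast_window(10L, 25L, 30L),
                 seed = seed, ...)
}

# 90-degree clockwise rotation on the pixel grid (exact).
rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
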