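# Independent oracles and fixture builders used across the test files.

# Mann-Whitney U by explicit pairwise counting (ties count one half)
brute_u <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) {
    s <- s + (xi > yj) + 0.5 * (xi == yj)
  }
  s
}

# all segment-pair intersections of two polylines, ordered by (i, s, j);
# independent elementwise arithmetic, no shared code with the package
brute_intersections <- function(p, q) {
  hits <- NULL
  for (i in seq_len(nrow(p) - 1L)) {
    for (j in seq_len(nrow(q) - 1L)) {
      a <- p[i, ]; b <- p[i + 1L, ]; c <- q[j, ]; d <- q[j + 1L, ]
      den <- (b[1] - a[1]) * (d[2] - c[2]) - (b[2] - a[2]) * (d[1] - c[1])
      if (abs(den) < 1e-12) next
      s <- ((c[1] - a[1]) * (d[2] - c[2]) - (c[2] - a[2]) * (d[1] - c[1])) / den
      t <- ((c[1] - a[1]) * (b[2] - a[2]) - (c[2] - a[2]) * (b[1] - a[1])) / den
      if (s >= -1e-12 && s <= 1 + 1e-12 && t >= -1e-12 && t <= 1 + 1e-12) {
        hits <- rbind(hits, c(i = i, s = unname(s), j = j,
                              x = unname(a[1] + s * (b[1] - a[1])),
                              y = unname(a[2] + s * (b[2] - a[2]))))
      }
    }
  }
  hits
}

# exhaustive optimal-threshold scan over a dense candidate grid
brute_best_g <- function(pos, neg, orientation) {
  u <- sort(unique(c(pos, neg)))
  cand <- c(u - 1e-9, (u[-length(u)] + u[-1]) / 2, u + 1e-9)
  g <- vapply(cand, function(th) {
    cls <- function(v) if (orientation == "high") v > th else v < th
    sqrt(mean(cls(pos)) * mean(!cls(neg)))
  }, 0)
  max(g)
}

# closed-form OLS via the normal equations
brute_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# rectangular force pulse recording fixture: both feet share a time base
rect_recording <- function(rate = 50, dur = 3,
                           left_on = c(1.0, 1.6), right_on = c(2.0, 2.6),
                           amp = 500) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  mk <- function(on) {
    F <- ifelse(t >= on[1] & t < on[2], amp, 0)
    data.frame(t = t, F = F,
               x = ifelse(F > 0, 0.05, NA), y = ifelse(F > 0, 0.5, NA))
  }
  insole_recording(mk(left_on), mk(right_on), rate = rate,
                   normalized = TRUE)
}

# template with scatter scaled by a factor (0 = noise free)
scaled_template <- function(cohort, factor) {
  tpl <- cohort_template(cohort)
  tpl$sigma <- tpl$sigma * factor
  tpl
}
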