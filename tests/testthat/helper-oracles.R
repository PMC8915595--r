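# independent least-squares oracle: explicit normal equations X'X b = X'y
normal_equations <- function(y, ...) {
  X <- cbind(1, ...)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# brute-force grid search over (intercept, slope) minimizing SSE
grid_search_line <- function(x, y, center, half_width = 2, steps = 81) {
  best <- c(NA, NA); best_sse <- Inf
  for (ic in seq(center[1] - half_width, center[1] + half_width,
                 length.out = steps))
    for (sl in seq(center[2] - half_width, center[2] + half_width,
                   length.out = steps)) {
      sse <- sum((y - ic - sl * x)^2)
      if (sse < best_sse) { best_sse <- sse; best <- c(ic, sl) }
    }
  best
}

tiny_standards <- function(slope = 16, intercept = -20,
                           tr = c(1.5, 2.1, 2.8, 3.4, 4.2), sd = 0) {
  data.frame(name = paste0("std", seq_along(tr)),
             retention_time_min = tr,
             chi_ref = intercept + slope * tr + rnorm(length(tr), 0, sd))
}
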