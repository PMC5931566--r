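# Independent brute-force oracles (plain loops, no shared code with the
# package implementations).

oracle_charge_hydropathy <- function(sequence, window, scale, charge,
                                     coef_h = 2.785, coef_q = 1,
                                     intercept = 1.151) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  half <- window %/% 2
  out <- numeric(L)
  for (i in seq_len(L)) {
    hs <- c()
    qs <- c()
    for (j in max(1, i - half):min(L, i + half)) {
      a <- chars[j]
      if (a != "X") {
        hs <- c(hs, scale[[a]])
        qs <- c(qs, charge[[a]])
      }
    }
    out[i] <- if (length(hs) == 0) NA_real_
              else coef_h * mean(hs) - coef_q * abs(mean(qs)) - intercept
  }
  out
}

oracle_pairwise_energy <- function(sequence, window, m, midpoint, slope) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  half <- window %/% 2
  out <- numeric(L)
  for (i in seq_len(L)) {
    a <- chars[i]
    if (a == "X") {
      out[i] <- NA_real_
      next
    }
    ctx <- c()
    for (j in max(1, i - half):min(L, i + half)) {
      if (j != i && chars[j] != "X") ctx <- c(ctx, chars[j])
    }
    if (length(ctx) == 0) {
      out[i] <- NA_real_
      next
    }
    e <- 0
    for (b in unique(ctx)) {
      e <- e + m[a, b] * (sum(ctx == b) / length(ctx))
    }
    out[i] <- 1 / (1 + exp((e - midpoint) / (-slope)))
  }
  out
}

# Longest run of TRUE by enumerating every (start, end) window.
oracle_longest_run <- function(calls) {
  best <- 0L
  n <- length(calls)
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (all(calls[s:e])) best <- max(best, e - s + 1L)
    }
  }
  best
}

# Least squares through the normal equations, written out by hand.
oracle_regression <- function(x, y, through_origin = FALSE) {
  if (through_origin) {
    a <- sum(x * y) / sum(x * x)
    fit <- a * x
    r2 <- 1 - sum((y - fit)^2) / sum(y^2)
    list(slope = a, intercept = NA_real_, r_squared = r2)
  } else {
    n <- length(x)
    a <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
    b <- mean(y) - a * mean(x)
    fit <- a * x + b
    r2 <- 1 - sum((y - fit)^2) / sum((y - mean(y))^2)
    list(slope = a, intercept = b, r_squared = r2)
  }
}

# Exhaustive truth-table oracle for the IDP criteria.
oracle_call_idp <- function(ldr, percent, mode, ldr_strict = 30,
                            ldr_low = 10, percent_min = 10) {
  if (ldr >= ldr_strict) return(TRUE)
  if (mode == "strict") return(FALSE)
  ldr >= ldr_low && ldr < ldr_strict && percent > percent_min
}
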