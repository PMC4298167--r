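# Independent brute-force oracles used to validate the package's
# implementations on small inputs.

# Prominence-based maxima finder, written as a direct transcription of the
# definition with explicit walks (O(n^2)): a plateau is a maximum when the
# values flanking it are strictly lower (at the ends of a non-periodic
# profile the missing flank is waived); its prominence is the height above
# the higher of the two minima reachable on each side without crossing a
# larger value (a waived flank does not bound it; on a circle with no
# larger value anywhere the walk covers everything, giving height minus
# global minimum). Plateau centers report at round-half-up of the midpoint.
brute_force_maxima <- function(x, tol, periodic = FALSE) {
  n <- length(x)
  if (length(unique(x)) == 1) return(integer(0))
  pos <- integer(0)
  if (!periodic) {
    i <- 1
    while (i <= n) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1
      v <- x[i]
      left_lower <- i == 1 || x[i - 1] < v
      right_lower <- j == n || x[j + 1] < v
      if (left_lower && right_lower) {
        lmin <- -Inf
        if (i > 1) {
          lmin <- Inf; k <- i - 1
          while (k >= 1 && x[k] <= v) { lmin <- min(lmin, x[k]); k <- k - 1 }
        }
        rmin <- -Inf
        if (j < n) {
          rmin <- Inf; k <- j + 1
          while (k <= n && x[k] <= v) { rmin <- min(rmin, x[k]); k <- k + 1 }
        }
        if (v - max(lmin, rmin) >= tol) pos <- c(pos, floor((i + j) / 2 + 0.5))
      }
      i <- j + 1
    }
  } else {
    at <- function(i) x[((i - 1) %% n) + 1]
    for (s in 1:n) {
      v <- x[s]
      if (at(s - 1) == v) next           # not the circular start of its plateau
      e <- s
      while (at(e + 1) == v) e <- e + 1  # terminates: not all values equal
      if (!(at(s - 1) < v && at(e + 1) < v)) next
      walk <- function(start, step) {
        m <- Inf; k <- start
        for (steps in 1:n) {
          if (at(k) > v) break
          m <- min(m, at(k)); k <- k + step
        }
        m
      }
      if (v - max(walk(s - 1, -1L), walk(e + 1, +1L)) >= tol) {
        pos <- c(pos, ((floor((s + e) / 2 + 0.5) - 1) %% n) + 1)
      }
    }
  }
  sort(unique(as.integer(pos)))
}

# Exhaustive Otsu: for every threshold t, split the raw values and compute
# the between-class variance from first principles. Tied maximizers (an
# empty gap between the classes) resolve to the midpoint of the tied range.
brute_force_otsu <- function(values) {
  v <- as.numeric(values)
  bcv <- rep(-Inf, 255)
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bcv[t + 1] <- w0 * w1 * (mean(lo) - mean(hi))^2
  }
  if (all(is.infinite(bcv))) return(127L)
  tied <- which(bcv == max(bcv)) - 1L
  as.integer(floor(mean(tied) + 0.5))
}

# Direct Gaussian kernel summation (mass oracle for impulse responses).
gaussian_kernel <- function(sigma) {
  half <- ceiling(3.5 * sigma)
  g <- outer(-half:half, -half:half,
             function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g / sum(g)
}
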