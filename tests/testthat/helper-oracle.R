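# Independent reference implementations used as oracles. Everything here is
# written as plain double loops / direct formulas, sharing no code with the
# package's vectorized paths.

# Euler totient, by direct gcd counting
phi_fn <- function(n) sum(vapply(seq_len(n), function(k) gcd2(k, n) == 1L, logical(1)))
gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# number of binary necklaces of length n (closed form)
necklace_count <- function(n) {
  divisors <- which(n %% seq_len(n) == 0)
  sum(vapply(divisors, function(d) phi_fn(d) * 2^(n / d), numeric(1))) / n
}

# minimum over cyclic shifts of the bit pattern of a raw code, via explicit
# bit-vector rotation
oracle_minimize <- function(code, n) {
  bits <- as.integer(intToBits(code)[1:n])
  best <- Inf
  for (s in 0:(n - 1)) {
    # bit i moves to position (i + s) mod n
    best <- min(best, sum(bits * 2^(((seq_len(n) - 1) + s) %% n)))
  }
  best
}

# dense labels for all raw codes, independently of the package's table
oracle_label_map <- function(n) {
  minimized <- vapply(0:(2^n - 1), oracle_minimize, numeric(1), n = n)
  reps <- sort(unique(minimized))
  match(minimized, reps) - 1L
}

# standard-weight bilinear interpolation of one channel at (x, y), 0-based
oracle_bilinear <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- min(x0 + 1, w - 1); y1 <- min(y0 + 1, h - 1)
  (1 - fx) * (1 - fy) * m[y0 + 1, x0 + 1] +
    fx * (1 - fy) * m[y0 + 1, x1 + 1] +
    (1 - fx) * fy * m[y1 + 1, x0 + 1] +
    fx * fy * m[y1 + 1, x1 + 1]
}

# naive per-pixel QDCP index image: double loop, no shared code
oracle_qdcp_labels <- function(orient, n, radius, t_o) {
  h <- dim(orient)[1]; w <- dim(orient)[2]
  band <- ceiling(radius)
  label_map <- oracle_label_map(n)
  out <- matrix(NA_integer_, h, w)
  for (r in band:(h - 1 - band)) {
    for (c in band:(w - 1 - band)) {
      center <- orient[r + 1, c + 1, ]
      code <- 0
      for (k in 0:(n - 1)) {
        ang <- 2 * pi * k / n
        x <- c + radius * cos(ang); y <- r + radius * sin(ang)
        v <- vapply(1:3, function(ch) oracle_bilinear(orient[, , ch], x, y),
                    numeric(1))
        nv <- sqrt(sum(v^2))
        if (nv <= 1e-12) v <- c(1, 0, 0) else v <- v / nv
        m <- sum(center * v)
        if (m > 1 - 1e-12) m <- 1
        if (m < -1 + 1e-12) m <- -1
        if (m < t_o) code <- code + 2^k
      }
      out[r + 1, c + 1] <- label_map[code + 1]
    }
  }
  out
}

# naive per-pixel LBP index image (neighbor >= center sets the bit)
oracle_lbp_labels <- function(scalar, n, radius) {
  h <- nrow(scalar); w <- ncol(scalar)
  band <- ceiling(radius)
  label_map <- oracle_label_map(n)
  out <- matrix(NA_integer_, h, w)
  for (r in band:(h - 1 - band)) {
    for (c in band:(w - 1 - band)) {
      center <- scalar[r + 1, c + 1]
      code <- 0
      for (k in 0:(n - 1)) {
        ang <- 2 * pi * k / n
        x <- c + radius * cos(ang); y <- r + radius * sin(ang)
        v <- oracle_bilinear(scalar, x, y)
        if (v >= center) code <- code + 2^k
      }
      out[r + 1, c + 1] <- label_map[code + 1]
    }
  }
  out
}

# Mann-Whitney AUC by brute force over positive-negative pairs
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
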