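# Parametric test shapes and independent oracle implementations.

circle_contour <- function(r = 1, n = 512L, cx = 0, cy = 0) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  oto_contour(cbind(cx + r * cos(th), cy + r * sin(th)))
}

ellipse_contour <- function(a = 2, b = 1, n = 512L, rot = 0) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  xy <- cbind(a * cos(th), b * sin(th))
  if (rot != 0) xy <- xy %*% matrix(c(cos(rot), sin(rot),
                                      -sin(rot), cos(rot)), 2L)
  oto_contour(xy)
}

rect_contour <- function(L = 3, W = 1, rot = 0, n_per_side = 64L) {
  s <- seq(0, 1, length.out = n_per_side + 1L)[-(n_per_side + 1L)]
  xy <- rbind(cbind(-L / 2 + L * s, -W / 2),
              cbind(L / 2, -W / 2 + W * s),
              cbind(L / 2 - L * s, W / 2),
              cbind(-L / 2, W / 2 - W * s))
  if (rot != 0) xy <- xy %*% matrix(c(cos(rot), sin(rot),
                                      -sin(rot), cos(rot)), 2L)
  oto_contour(xy)
}

# star-shaped harmonic blob used for descriptor tests
blob_contour <- function(seed = 1L, n = 512L, base = c(`2` = 0.15, `3` = 0.06),
                         noise_sd = 0.02, crenation = 0) {
  set.seed(seed)
  th <- 2 * pi * (seq_len(n) - 1L) / n
  r <- rep(1, n)
  for (k in as.integer(names(base))) r <- r + base[[as.character(k)]] * cos(k * th)
  for (k in 4:8) r <- r + rnorm(1L, 0, noise_sd) * cos(k * th + runif(1L, 0, 2 * pi))
  if (crenation > 0) r <- r + crenation * cos(24 * th + runif(1L, 0, 2 * pi))
  oto_contour(cbind(r * cos(th), r * sin(th)))
}

rotate_xy <- function(xy, a) xy %*% matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)

signed_area_of <- function(ct) {
  xy <- unclass(ct)
  x <- xy[, 1L]; y <- xy[, 2L]
  sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y) / 2
}

# --- independent oracles ---

# Welch t statistic from definition sums at long precision
welch_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  mx <- sum(x) / nx; my <- sum(y) / ny
  vx <- sum((x - mx)^2) / (nx - 1); vy <- sum((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Pearson r from definition sums
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Tukey HSD adjusted p for balanced one-way data, direct from the
# studentized-range distribution
tukey_oracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ns <- table(groups)
  ms <- tapply(values, groups, mean)
  df <- length(values) - k
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / df
  pairs <- utils::combn(levels(groups), 2L)
  out <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se <- sqrt(mse / 2 * (1 / ns[[i]] + 1 / ns[[j]]))
    q <- abs(ms[[i]] - ms[[j]]) / se
    stats::ptukey(q, k, df, lower.tail = FALSE)
  })
  names(out) <- paste(pairs[2L, ], pairs[1L, ], sep = "-")
  out
}

# exact 1-D k-means (minimum within-cluster SS) by dynamic programming
kmeans1d_oracle <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssq <- function(i, j) {  # within-SS of x[i..j]
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in seq_len(n)) D[1L, j] <- ssq(1L, j)
  if (k > 1L) for (m in 2:k) for (j in m:n) {
    for (i in m:j) {
      v <- D[m - 1L, i - 1L] + ssq(i, j)
      if (v < D[m, j]) { D[m, j] <- v; B[m, j] <- i }
    }
  }
  bounds <- integer(k + 1L); bounds[k + 1L] <- n
  j <- n
  for (m in k:2) { j <- B[m, j] - 1L; bounds[m] <- j }
  lab <- integer(n)
  for (m in seq_len(k)) lab[(bounds[m] + 1L):bounds[m + 1L]] <- m
  list(x = x, labels = lab, ss = D[k, n])
}
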