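## Small in-code fixtures shared across test files.

make_counts <- function(n_otu = 5, n_samp = 6, seed = 1, max_count = 50) {
  set.seed(seed)
  m <- matrix(sample.int(max_count + 1L, n_otu * n_samp, replace = TRUE) - 1L,
              n_otu, n_samp,
              dimnames = list(sprintf("OTU%02d", seq_len(n_otu)),
                              sprintf("S%02d", seq_len(n_samp))))
  m
}

## metadata for n_mz + n_dz complete families; sample ids S01, S02, ...
make_records <- function(n_mz = 2, n_dz = 1, seed = 1) {
  set.seed(seed)
  n_fam <- n_mz + n_dz
  data.frame(
    sample_id = sprintf("S%02d", seq_len(2 * n_fam)),
    family_id = sprintf("F%02d", rep(seq_len(n_fam), each = 2)),
    zygosity = rep(c("MZ", "DZ"), c(2 * n_mz, 2 * n_dz)),
    gender = rep(sample(c("F", "M"), n_fam, replace = TRUE), each = 2),
    age = rep(round(runif(n_fam, 20, 80), 1), each = 2),
    stringsAsFactors = FALSE
  )
}

## independent brute-force BH step-up, straight from the definition
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

## exact two-sided Mann-Whitney p by full enumeration of group labelings
mwu_enumerate <- function(x, y) {
  u_stat <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pool <- c(x, y)
  m <- length(x)
  obs <- u_stat(x, y)
  combos <- utils::combn(length(pool), m)
  mu <- m * length(y) / 2
  us <- apply(combos, 2, function(idx)
    u_stat(pool[idx], pool[-idx]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

## ACE log-likelihood by per-pair 2x2 matrix inversion (independent of the
## package's sufficient-statistic implementation)
ace_loglik_bruteforce <- function(a, c, e, mu, data) {
  v <- a^2 + c^2 + e^2
  ll <- 0
  for (grp in list(list(m = data$mz, cv = a^2 + c^2),
                   list(m = data$dz, cv = a^2 / 2 + c^2))) {
    S <- matrix(c(v, grp$cv, grp$cv, v), 2)
    Si <- solve(S)
    for (i in seq_len(nrow(grp$m))) {
      d <- grp$m[i, ] - mu
      ll <- ll - log(2 * pi) - 0.5 * log(det(S)) -
        0.5 * drop(t(d) %*% Si %*% d)
    }
  }
  ll
}

## dense-grid Box-Cox profile-likelihood argmax (brute-force oracle)
boxcox_grid_oracle <- function(y, design, step = 0.01, range = c(-5, 5)) {
  grid <- seq(range[1], range[2], by = step)
  qrx <- qr(design)
  sly <- sum(log(y))
  n <- length(y)
  ll <- vapply(grid, function(l) {
    yt <- if (abs(l) < 1e-8) log(y) else (y^l - 1) / l
    rss <- sum(qr.resid(qrx, yt)^2)
    -(n / 2) * log(rss / n) + (l - 1) * sly
  }, numeric(1))
  grid[which.max(ll)]
}
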