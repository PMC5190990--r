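# Shared fixtures and independent oracles, built in code at test time.

# A two-color frame: top rows sky-like (pale blue), bottom rows canopy-like
# (dark green); exact colors are fixed so expected values are reproducible.
two_color_frame <- function(height = 20L, width = 20L, veg_rows = height %/% 2L) {
  img <- array(0, dim = c(height, width, 3L))
  for (i in seq_len(height)) {
    col <- if (i > height - veg_rows) c(0.10, 0.45, 0.12) else
      c(0.70, 0.80, 0.95)
    img[i, , 1L] <- col[1L]; img[i, , 2L] <- col[2L]; img[i, , 3L] <- col[3L]
  }
  rgb_image(img)
}

constant_frame <- function(rgb, height = 8L, width = 8L) {
  img <- array(rep(rgb, each = height * width), dim = c(height, width, 3L))
  rgb_image(img)
}

# Exhaustive-split oracle for the two-class break: evaluates every
# contiguous split with plain mean/sum arithmetic.
jenks_oracle <- function(values) {
  v <- sort(values)
  n <- length(v)
  ssd <- vapply(seq_len(n - 1L), function(k) {
    lo <- v[1:k]; hi <- v[(k + 1L):n]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1L))
  k <- which.min(ssd)
  list(split_index = k, ssd = ssd[k])
}

# Direct-summation oracles for the profile indices.
cog_oracle <- function(ci) {
  num <- 0; den <- 0
  for (s in 1:15) { num <- num + s * ci[s]; den <- den + ci[s] }
  num / den
}
moi_oracle <- function(ci) {
  cog <- cog_oracle(ci)
  tot <- 0
  for (s in 1:15) tot <- tot + ci[s] * (s - cog)^2
  tot
}

# Closed-form OLS via the normal equations (independent of lm.fit).
ols_oracle <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  m <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  q <- (sy - m * sx) / n
  c(slope = m, intercept = q)
}

# Per-cell brute-force IDW.
idw_oracle <- function(px, py, pv, cx, cy, power = 2, radius = Inf) {
  d <- sqrt((px - cx)^2 + (py - cy)^2)
  if (any(d < 1e-9)) return(mean(pv[d < 1e-9]))
  nb <- d <= radius
  if (!any(nb)) return(NA_real_)
  w <- 1 / d[nb]^power
  sum(w * pv[nb]) / sum(w)
}

survey_columns_for_test <- function() {
  c("timestamp", "lat", "lon", "side", "vine_id", "rh", "at", "us",
    "n_satellites", paste0("ci_s", 1:15), paste0("st_s", 1:16))
}

# Minimal valid survey record data frame.
make_survey_df <- function(n = 10L, ci_base = 600) {
  df <- data.frame(
    timestamp = as.numeric(seq_len(n)),
    lat = 45.1 + seq_len(n) * 1e-5,
    lon = 9.6 + seq_len(n) * 1e-5,
    side = rep(c("left", "right"), length.out = n),
    vine_id = sprintf("V%02d", (seq_len(n) + 1L) %/% 2L),
    rh = 60 + seq_len(n) * 0.1,
    at = 24 + seq_len(n) * 0.01,
    us = rep(110.5, n),
    n_satellites = rep(10L, n),
    stringsAsFactors = FALSE)
  for (s in 1:15) df[[paste0("ci_s", s)]] <- ci_base + s
  for (s in 1:16) df[[paste0("st_s", s)]] <- 18 + s * 0.25
  df
}
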