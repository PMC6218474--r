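# Independent brute-force oracles. Deliberately scalar, loop-based and
# written from the scoring definitions, not from the package internals.

# Per-cell HFP by summing independently computed layer scores.
oracle_hfp <- function(stack) {
  g <- stack$grid
  L <- lapply(stack$layers, function(l) l$values)
  # night-light decile of one value given all lit values: lower decile on
  # ties via (count strictly below + 1) as the rank.
  lit <- L$nightlights[!is.na(L$nightlights) & L$nightlights > 0]
  night_score <- function(v) {
    if (is.na(v)) return(NA_real_)
    if (v <= 0) return(0)
    ceiling(10 * (sum(lit < v) + 1) / length(lit))
  }
  road_score <- function(d) {
    if (is.na(d)) return(NA_real_)
    if (d <= 0.5) 8
    else if (d <= 15) 4 * exp(-(log(4 / 0.25) / 14.5) * (d - 0.5))
    else 0
  }
  water_score <- function(d) {
    if (is.na(d)) return(NA_real_)
    if (d <= 0) 4
    else if (d <= 15) 4 * exp(-(log(4 / 0.25) / 15) * d)
    else 0
  }
  out <- matrix(NA_real_, g$nrow, g$ncol)
  for (i in seq_len(g$nrow)) {
    for (j in seq_len(g$ncol)) {
      s <- 10 * L$built[i, j] + 7 * L$crop[i, j] + 4 * L$pasture[i, j] +
        min(10, 3.333 * log10(L$popdensity[i, j] + 1)) +
        night_score(L$nightlights[i, j]) +
        (if (is.na(L$railways[i, j])) NA_real_
         else if (L$railways[i, j] <= 0.5) 8 else 0) +
        road_score(L$roads[i, j]) + water_score(L$waterways[i, j])
      out[i, j] <- if (is.na(s)) NA_real_ else min(50, max(0, floor(s + 0.5)))
    }
  }
  out
}

# Winding-number point-in-polygon (different algorithm from the package's
# crossing-number implementation).
oracle_point_in_polygon <- function(px, py, poly) {
  nv <- nrow(poly)
  vapply(seq_along(px), function(k) {
    wn <- 0
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1L else i + 1L
      x1 <- poly[i, 1]; y1 <- poly[i, 2]
      x2 <- poly[j, 1]; y2 <- poly[j, 2]
      if (y1 <= py[k]) {
        if (y2 > py[k] &&
            (x2 - x1) * (py[k] - y1) - (px[k] - x1) * (y2 - y1) > 0)
          wn <- wn + 1
      } else {
        if (y2 <= py[k] &&
            (x2 - x1) * (py[k] - y1) - (px[k] - x1) * (y2 - y1) < 0)
          wn <- wn - 1
      }
    }
    wn != 0
  }, logical(1))
}

oracle_rasterize <- function(poly, grid) {
  cc <- cell_centers(grid)
  cc$cell[oracle_point_in_polygon(cc$x, cc$y, poly)]
}

# Per-cell loop versions of the overlap statistics.
oracle_profile <- function(cells, hfp) {
  vals <- hfp$values[cells]
  vals <- vals[!is.na(vals)]
  sapply(0:50, function(v) sum(vals <= v) / length(vals))
}

oracle_extent_above <- function(cells, hfp, t) {
  vals <- hfp$values[cells]
  vals <- vals[!is.na(vals)]
  n <- 0
  for (v in vals) if (v > t) n <- n + 1
  n / length(vals)
}

oracle_extent_change <- function(cells, h93, h09, t, clamp) {
  a <- h93$values[cells]; b <- h09$values[cells]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n93 <- 0; n09 <- 0
  for (k in seq_along(a)) {
    bf <- if (clamp && b[k] < a[k]) a[k] else b[k]
    if (a[k] > t) n93 <- n93 + 1
    if (bf > t) n09 <- n09 + 1
  }
  (n09 - n93) / length(a)
}

# Exact rank-sum tail probability by full enumeration (independent of the
# package's enumeration: works on the raw values).
oracle_ranksum_p <- function(a, b, alternative = "greater") {
  pooled <- c(a, b)
  m <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)])
  combs <- utils::combn(length(pooled), m)
  ws <- apply(combs, 2, function(ix) sum(r[ix]))
  if (alternative == "greater") mean(ws >= w_obs) else mean(ws <= w_obs)
}
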