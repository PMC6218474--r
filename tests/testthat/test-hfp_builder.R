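g5 <- hfp_grid(5, 5)

test_that("land-use, density and light layers score per the index rules", {
  z <- matrix(0, 5, 5)
  b <- z; b[2, 2] <- 1
  expect_equal(standardize_layer("built", b, g5)$values[2, 2], 10)
  expect_equal(standardize_layer("crop", b, g5)$values[2, 2], 7)
  expect_equal(standardize_layer("pasture", b, g5)$values[2, 2], 4)
  expect_equal(standardize_layer("built", b, g5)$values[1, 1], 0)

  d <- z; d[1, 1] <- 100; d[1, 2] <- 1500; d[2, 1] <- 999
  s <- standardize_layer("popdensity", d, g5)$values
  expect_equal(s[3, 3], 0)                       # zero density
  expect_equal(s[1, 1], 3.333 * log10(101))      # log-scaled: 6.68
  expect_equal(s[1, 1], 6.68, tolerance = 1e-3)
  expect_equal(s[1, 2], 10)                      # > 1000 people/km2
  expect_lt(s[2, 1], 10)

  expect_error(standardize_layer("popdensity", z - 1, g5), "negative")
  expect_error(standardize_layer("built", z + 0.5, g5), "non-boolean")
  expect_error(standardize_layer("bogus", z, g5), "unknown layer")
})

test_that("night lights score by deciles over lit cells, ties to lower decile", {
  v <- matrix(0, 5, 5)
  v[1, 1:5] <- c(1, 2, 3, 4, 5)
  v[2, 1:5] <- c(6, 7, 8, 9, 10)
  s <- standardize_layer("nightlights", v, g5)$values
  expect_equal(s[1, ], 1:5)        # 10 lit cells: one per decile
  expect_equal(s[2, ], 6:10)
  expect_equal(s[3, 3], 0)         # unlit
  # ties share the lower decile
  v2 <- matrix(0, 5, 5); v2[1, 1:4] <- c(5, 5, 5, 9)
  s2 <- standardize_layer("nightlights", v2, g5)$values
  expect_equal(s2[1, 1], s2[1, 2])
  expect_equal(s2[1, 1], ceiling(10 * 1 / 4))
  expect_equal(s2[1, 4], 10)
  # all scores always within [0, 10]
  set.seed(42)
  v3 <- matrix(rexp(25), 5, 5)
  s3 <- standardize_layer("nightlights", v3, g5)$values
  expect_true(all(s3 >= 0 & s3 <= 10))
})

test_that("distance decay: direct buffer, closed-form interior, hard cutoff", {
  roads <- default_decay_params("roads")
  expect_equal(distance_decay_score(0.3, roads), 8)     # inside 500 m
  expect_equal(distance_decay_score(20, roads), 0)      # beyond 15 km
  # halfway through the decay window: 4 * exp(-k * 7.25) with
  # k = log(16)/14.5, i.e. 4 * exp(-log(16)/2) = 1 exactly
  expect_equal(distance_decay_score(0.5 + 7.25, roads), 1)
  expect_equal(distance_decay_score(15, roads), 0.25)   # rounds to 0
  ww <- default_decay_params("waterways")
  expect_equal(distance_decay_score(0, ww), 4)          # bank-adjacent
  expect_equal(distance_decay_score(15, ww), 0.25)
  expect_error(distance_decay_score(-1, roads), "negative")
  # nonincreasing in distance
  d <- seq(0, 30, by = 0.1)
  expect_true(all(diff(distance_decay_score(d, roads)) <= 1e-12))
})

test_that("build_hfp sums standardized layers into an integer 0-50 map", {
  expect_equal(build_hfp(zero_stack(g5))$values, matrix(0, 5, 5))
  crop <- matrix(0, 5, 5); crop[3, 3] <- 1
  expect_equal(build_hfp(one_layer_stack(g5, "crop", crop))$values[3, 3], 7)
  # all pressures maximal in one cell (land-use exclusivity respected) -> 50
  ls <- zero_layers(g5)
  ls$built[1, 1] <- 1
  ls$popdensity[1, 1] <- 2000
  ls$nightlights[1, 1] <- 100       # only lit cell: top decile
  ls$railways[1, 1] <- 0
  ls$roads[1, 1] <- 0
  ls$waterways[1, 1] <- 0
  h <- build_hfp(pressure_stack(ls, g5))
  expect_equal(h$values[1, 1], 50)
  expect_true(all(h$values >= 0 & h$values <= 50))
  expect_true(all(h$values == round(h$values)))
})

test_that("stack validation: exclusivity, missing layers, grid mismatch", {
  ls <- zero_layers(g5)
  ls$built[1, 1] <- 1; ls$crop[1, 1] <- 1
  expect_error(pressure_stack(ls, g5), "mutually exclusive")
  expect_error(pressure_stack(zero_layers(g5)[-1], g5), "missing: built")
  ls2 <- lapply(zero_layers(g5), raster_layer, grid = g5)
  ls2$crop <- raster_layer(matrix(0, 4, 4), hfp_grid(4, 4))
  expect_error(pressure_stack(ls2), "grid mismatch")
})

test_that("build_hfp equals the brute-force per-cell oracle on random stacks", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 20
    g <- hfp_grid(n, n)
    lu <- sample(0:3, n * n, replace = TRUE)  # 0 none, 1 built, 2 crop, 3 pasture
    ls <- list(built = matrix((lu == 1) * 1, n, n),
               crop = matrix((lu == 2) * 1, n, n),
               pasture = matrix((lu == 3) * 1, n, n),
               popdensity = matrix(rexp(n * n, 1 / 200), n, n),
               nightlights = matrix(rexp(n * n) * rbinom(n * n, 1, 0.4), n, n),
               railways = matrix(runif(n * n, 0, 30), n, n),
               roads = matrix(runif(n * n, 0, 30), n, n),
               waterways = matrix(runif(n * n, 0, 30), n, n))
    stack <- pressure_stack(ls, g, epoch = 1993)
    expect_equal(build_hfp(stack)$values, oracle_hfp(stack))
  }
})

test_that("build_hfp is monotone in any raw layer", {
  set.seed(9)
  g <- hfp_grid(8, 8)
  ls <- zero_layers(g)
  ls$popdensity <- matrix(rexp(64, 1 / 50), 8, 8)
  ls$roads <- matrix(runif(64, 0, 30), 8, 8)
  base <- build_hfp(pressure_stack(ls, g))
  for (k in 1:10) {
    i <- sample(8, 1); j <- sample(8, 1)
    ls2 <- ls
    ls2$popdensity[i, j] <- ls2$popdensity[i, j] * 5 + 100
    ls2$roads[i, j] <- 0  # closer road = more pressure
    bumped <- build_hfp(pressure_stack(ls2, g))
    expect_gte(bumped$values[i, j], base$values[i, j])
  }
})

test_that("nodata in any layer propagates to the HFP map", {
  ls <- zero_layers(g5)
  ls$popdensity[2, 3] <- NA
  h <- build_hfp(pressure_stack(ls, g5))
  expect_true(is.na(h$values[2, 3]))
  expect_equal(sum(is.na(h$values)), 1)
})

test_that("hfp_change: deltas, transition matrix, and the no-change clamp", {
  g3 <- hfp_grid(3, 3)
  a <- raster_layer(matrix(c(0, 1, 2, 3, 4, 5, 6, 7, 8), 3, 3), g3,
                    epoch = 1993)
  # identical maps -> zero deltas, purely diagonal matrix
  ch0 <- hfp_change(a, raster_layer(a$values, g3, epoch = 2009))
  expect_true(all(ch0$delta$values == 0))
  expect_equal(sum(ch0$matrix), 9)
  expect_equal(sum(diag(ch0$matrix)), 9)

  b_vals <- matrix(c(5, 1, 2, 2, 6, 5, 6, 9, 4), 3, 3)  # mix of up/down/flat
  b <- raster_layer(b_vals, g3, epoch = 2009)
  ch <- hfp_change(a, b, clamp_decreases = TRUE)
  # cell (1,2): 3 -> 2 decreased; clamped to "no change", counted at (3,3)
  expect_equal(ch$delta$values[1, 2], 0)
  expect_equal(ch$matrix["3", "3"], 1L)
  # brute-force tally of all 9 pairs under the clamp rule
  expected <- matrix(0L, 51, 51, dimnames = list(initial = 0:50, final = 0:50))
  for (k in 1:9) {
    init <- a$values[k]; fin <- max(a$values[k], b_vals[k])
    expected[init + 1, fin + 1] <- expected[init + 1, fin + 1] + 1L
  }
  expect_equal(ch$matrix, expected)
  # no mass below the diagonal when clamped
  expect_equal(sum(ch$matrix[lower.tri(ch$matrix)]), 0)
  expect_true(all(ch$delta$values >= 0))
  # unclamped keeps the decreases
  ch2 <- hfp_change(a, b, clamp_decreases = FALSE)
  expect_equal(ch2$delta$values[1, 2], -1)
  expect_gt(sum(ch2$matrix[lower.tri(ch2$matrix)]), 0)
})

test_that("hfp_change rejects mismatched grids and epochs", {
  g3 <- hfp_grid(3, 3)
  a <- raster_layer(matrix(0, 3, 3), g3, epoch = 1993)
  expect_error(hfp_change(a, raster_layer(matrix(0, 4, 4), hfp_grid(4, 4),
                                          epoch = 2009)),
               "grid mismatch")
  expect_error(hfp_change(a, raster_layer(matrix(0, 3, 3), g3, epoch = 1993)),
               "epoch mismatch")
  expect_error(hfp_change(a, raster_layer(matrix(0.5, 3, 3), g3,
                                          epoch = 2009)),
               "integer")
})
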