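test_that("cohens_d: hand values, symmetry, degenerate flags", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)  # pooled SD = 1
  expect_equal(cohens_d(c(3, 4, 5), c(1, 2, 3)), 2)
  expect_warning(d <- cohens_d(c(2, 2), c(2, 2)), "zero pooled SD")
  expect_true(is.nan(d))
  expect_error(cohens_d(1, c(1, 2)), "n >= 2")
})

test_that("rank_test: exact enumeration, symmetry and oracle agreement", {
  # complete separation of 3 vs 3: 1 of choose(6,3) = 20 arrangements
  expect_equal(rank_test(c(4, 5, 6), c(1, 2, 3), "greater"), 1 / 20)
  expect_equal(rank_test(c(4, 5, 6), c(1, 2, 3), "less"), 1)
  # identical multisets: either one-sided p is >= 0.5
  expect_gte(rank_test(c(1, 2, 3), c(3, 1, 2), "greater"), 0.5)
  expect_gte(rank_test(c(1, 2, 3), c(3, 1, 2), "less"), 0.5)
  expect_error(rank_test(c(2, 2), c(2, 2, 2)), "tied")
  # agreement with the independent enumeration oracle, with and without ties
  set.seed(31)
  for (i in 1:5) {
    a <- sample(1:8, 5, replace = TRUE)
    b <- sample(2:9, 5, replace = TRUE)
    if (length(unique(c(a, b))) == 1) next
    expect_equal(rank_test(a, b, "greater"), oracle_ranksum_p(a, b, "greater"))
    expect_equal(rank_test(a, b, "less"), oracle_ranksum_p(a, b, "less"))
  }
})

test_that("normal approximation tracks the exact tail at n = 6 + 6", {
  set.seed(7)
  for (i in 1:5) {
    a <- rnorm(6, 0.5)
    b <- rnorm(6)
    exact <- rank_test(a, b, "greater")   # 12 values -> enumeration path
    approx <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "greater", exact = FALSE,
                         correct = TRUE)$p.value)
    expect_lt(abs(exact - approx), 0.01)
  }
})

test_that("swapping group labels negates d and mirrors the one-sided p", {
  set.seed(13)
  for (i in 1:5) {
    a <- rnorm(15, 0.3); b <- rnorm(12)
    expect_equal(cohens_d(a, b), -cohens_d(b, a))
    expect_equal(rank_test(a, b, "greater"), rank_test(b, a, "less"))
  }
})

make_overlaps <- function(deltas, t = 0:2) {
  # one species per element of `deltas`, same delta at every threshold
  do.call(rbind, lapply(seq_along(deltas), function(i)
    data.frame(species_id = names(deltas)[i], t = t,
               extent93 = 0.2, extent09 = 0.2 + unname(deltas[i]),
               delta = unname(deltas[i]), clamped = TRUE)))
}

test_that("group_sweep reproduces hand-computed group means", {
  deltas <- c(a = 0.10, b = 0.30, c = 0.02, d = 0.04, e = 0.06, f = 0.20)
  ov <- make_overlaps(deltas)
  lab <- data.frame(species_id = names(deltas),
                    risk_class = c("high-risk", "high-risk", "low-risk",
                                   "low-risk", "low-risk", "high-risk"))
  sw <- group_sweep(ov, lab)
  expect_equal(nrow(sw), 3)
  expect_equal(sw$mean_delta_pos, rep(mean(c(0.10, 0.30, 0.20)), 3))
  expect_equal(sw$mean_delta_neg, rep(mean(c(0.02, 0.04, 0.06)), 3))
  expect_equal(sw$n_pos, rep(3L, 3))
  expect_equal(sw$d_delta,
               rep(cohens_d(c(0.1, 0.3, 0.2), c(0.02, 0.04, 0.06)), 3))
  expect_equal(sw$p_delta,
               rep(rank_test(c(0.1, 0.3, 0.2), c(0.02, 0.04, 0.06),
                             "greater"), 3))
})

test_that("identical groups give d = 0; singleton groups flag the interval", {
  deltas <- c(a = 0.1, b = 0.2, c = 0.1, d = 0.2)
  ov <- make_overlaps(deltas)
  lab <- data.frame(species_id = names(deltas),
                    risk_class = c("high-risk", "high-risk",
                                   "low-risk", "low-risk"))
  sw <- group_sweep(ov, lab)
  expect_equal(sw$d_delta, rep(0, 3))
  lab1 <- data.frame(species_id = names(deltas),
                     risk_class = c("high-risk", rep("low-risk", 3)))
  sw1 <- group_sweep(ov, lab1)
  expect_true(all(is.na(sw1$hw_delta_pos)))  # n = 1: undefined, flagged NA
  lab0 <- data.frame(species_id = names(deltas),
                     risk_class = rep("low-risk", 4))
  expect_error(group_sweep(ov, lab0), "empty group")
})

test_that("interval half-width shrinks as 1/sqrt(n)", {
  set.seed(99)
  hw <- sapply(c(25, 100, 400), function(n) {
    x <- rnorm(n)
    ids <- paste0("s", seq_len(n + 2))
    deltas <- setNames(c(x, 0.5, 0.6), ids)
    ov <- make_overlaps(deltas, t = 0)
    lab <- data.frame(species_id = ids,
                      risk_class = c(rep("low-risk", n), "high-risk",
                                     "high-risk"))
    group_sweep(ov, lab)$hw_delta_neg[1]
  })
  slope <- coef(lm(log(hw) ~ log(c(25, 100, 400))))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.15)
})

test_that("bootstrap intervals are seeded and close to the normal ones", {
  set.seed(4)
  n <- 60
  ids <- paste0("s", 1:n)
  deltas <- setNames(c(rnorm(n / 2, 0.3, 0.1), rnorm(n / 2, 0.1, 0.1)), ids)
  ov <- make_overlaps(deltas, t = 0)
  lab <- data.frame(species_id = ids,
                    risk_class = rep(c("high-risk", "low-risk"), each = n / 2))
  b1 <- group_sweep(ov, lab, conf = "bootstrap", seed = 42)
  b2 <- group_sweep(ov, lab, conf = "bootstrap", seed = 42)
  expect_identical(b1$hw_delta_pos, b2$hw_delta_pos)
  nm <- group_sweep(ov, lab)
  expect_equal(b1$hw_delta_pos, nm$hw_delta_pos, tolerance = 0.25)
})

test_that("effect_profile peaks and tie-breaks", {
  sw <- structure(data.frame(t = 1:3, d_extent = c(0.1, 0.4, 0.2),
                             d_delta = c(0.3, 0.3, 0.3)),
                  class = c("group_sweep", "data.frame"))
  ep <- effect_profile(sw)
  expect_equal(ep$t_peak_extent, 2)
  expect_equal(ep$t_peak_delta, 1)  # flat profile -> lowest threshold
  sw$d_extent <- NaN
  sw$d_delta <- NaN
  expect_error(effect_profile(sw), "non-finite")
  # |d| is maximized, sign ignored
  sw2 <- structure(data.frame(t = 1:3, d_extent = c(-0.9, 0.4, 0.2),
                              d_delta = c(0, -0.2, 0.1)),
                   class = c("group_sweep", "data.frame"))
  expect_equal(effect_profile(sw2)$t_peak_extent, 1)
  expect_equal(effect_profile(sw2)$t_peak_delta, 2)
})
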