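#' Cohen's d standardized mean difference
#'
#' \code{(mean(a) - mean(b)) / s_pooled} with the pooled standard deviation
#' \code{sqrt(((nA-1) sA^2 + (nB-1) sB^2) / (nA + nB - 2))}.
#'
#' @param a,b numeric samples (each of size >= 2).
#' @return d; \code{NaN} (with a warning) when the pooled SD is zero.
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2 for Cohen's d")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) {
    warning("zero pooled SD; Cohen's d undefined")
    return(NaN)
  }
  (mean(a) - mean(b)) / sp
}

#' One-sided rank-sum test for two independent samples
#'
#' Wilcoxon-Mann-Whitney location test. For small samples
#' (\code{nA + nB <= 12}) the p-value comes from exact enumeration of all
#' assignments of the pooled ranks (ties handled naturally); otherwise the
#' normal approximation with tie correction is used.
#'
#' @param a,b numeric samples.
#' @param alternative \code{"greater"} tests whether \code{a} tends larger
#'   than \code{b}; \code{"less"} the reverse.
#' @return one-sided p-value.
#' @export
rank_test <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L)
    stop("all values tied across both groups; rank test undefined")
  m <- length(a); n <- length(b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)])
  if (m + n <= 12) {
    idx <- utils::combn(m + n, m)
    w_perm <- colSums(matrix(r[idx], nrow = m))
    if (alternative == "greater") mean(w_perm >= w_obs)
    else mean(w_perm <= w_obs)
  } else {
    suppressWarnings(
      stats::wilcox.test(a, b, alternative = alternative, exact = FALSE,
                         correct = TRUE)$p.value)
  }
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# d flagged NA when undefined (singleton group or zero pooled SD)
safe_d <- function(a, b) {
  tryCatch(suppressWarnings(cohens_d(a, b)), error = function(e) NA_real_)
}

half_width <- function(x, conf, n_boot) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  if (conf == "normal") {
    1.96 * stats::sd(x) / sqrt(length(x))
  } else {
    means <- vapply(seq_len(n_boot), function(i)
      mean(sample(x, replace = TRUE)), numeric(1))
    diff(stats::quantile(means, c(0.025, 0.975), names = FALSE)) / 2
  }
}

#' Per-threshold group curves, effect sizes and rank tests
#'
#' For every threshold t, summarizes the two outcome groups (mean delta and
#' mean extents with 95% interval half-widths) and compares them: Cohen's d of
#' the final-epoch extent and of the extent delta (positive group minus
#' reference group), and the one-sided rank-sum p-value for the hypothesis
#' that the positive group's deltas are larger.
#'
#' @param overlaps long overlap table from \code{\link{overlap_table}}.
#' @param labels data.frame with \code{species_id} and the grouping column.
#' @param by grouping column: \code{"risk_class"} (positive group
#'   \code{"high-risk"}) or \code{"uplist_class"} (positive group
#'   \code{"uplisted"}).
#' @param conf \code{"normal"} for mean +/- 1.96 SE, \code{"bootstrap"} for a
#'   seeded percentile bootstrap of the group mean.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap option.
#' @return data.frame of class \code{group_sweep}, one row per threshold, with
#'   group means/half-widths/sizes and columns \code{d_extent},
#'   \code{d_delta}, \code{p_delta}.
#' @export
group_sweep <- function(overlaps, labels, by = c("risk_class", "uplist_class"),
                        conf = c("normal", "bootstrap"), n_boot = 1000,
                        seed = NULL) {
  by <- match.arg(by)
  conf <- match.arg(conf)
  pos <- if (by == "risk_class") "high-risk" else "uplisted"
  neg <- if (by == "risk_class") "low-risk" else "not-uplisted"
  df <- merge(overlaps, labels[, c("species_id", by)], by = "species_id")
  if (!nrow(df)) stop("no labelled species in overlap table")
  grp <- df[[by]]
  bad <- setdiff(unique(grp), c(pos, neg))
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  ts <- sort(unique(df$t))
  with_seed(seed, {
    rows <- lapply(ts, function(tt) {
      d_t <- df[df$t == tt, ]
      hi <- d_t[grp[df$t == tt] == pos, ]
      lo <- d_t[grp[df$t == tt] == neg, ]
      if (!nrow(hi) || !nrow(lo))
        stop("empty group at threshold ", tt)
      data.frame(
        t = tt,
        n_pos = nrow(hi), n_neg = nrow(lo),
        mean_delta_pos = mean(hi$delta), mean_delta_neg = mean(lo$delta),
        hw_delta_pos = half_width(hi$delta, conf, n_boot),
        hw_delta_neg = half_width(lo$delta, conf, n_boot),
        mean_ext93_pos = mean(hi$extent93), mean_ext93_neg = mean(lo$extent93),
        mean_ext09_pos = mean(hi$extent09), mean_ext09_neg = mean(lo$extent09),
        d_extent = safe_d(hi$extent09, lo$extent09),
        d_delta = safe_d(hi$delta, lo$delta),
        p_delta = tryCatch(rank_test(hi$delta, lo$delta, "greater"),
                           error = function(e) NA_real_))
    })
    out <- do.call(rbind, rows)
    structure(out, class = c("group_sweep", "data.frame"),
              groups = c(positive = pos, reference = neg), by = by,
              conf = conf)
  })
}

#' Thresholds of maximal effect size
#'
#' Locates the threshold maximizing |Cohen's d| separately for the
#' final-epoch extent and for the extent delta. Ties break toward the lowest
#' threshold.
#'
#' @param sweep a \code{group_sweep}.
#' @return list with \code{t_peak_extent} and \code{t_peak_delta}.
#' @export
effect_profile <- function(sweep) {
  stopifnot(inherits(sweep, "group_sweep"))
  peak <- function(d) {
    ok <- is.finite(d)
    if (!any(ok)) stop("all effect sizes non-finite")
    tt <- sweep$t[ok]
    dd <- abs(d[ok])
    tt[which.max(dd)]  # which.max returns the first maximum: lowest t
  }
  list(t_peak_extent = peak(sweep$d_extent),
       t_peak_delta = peak(sweep$d_delta))
}
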