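#' Transition-catalysis trend test
#'
#' Tests, for every ordered state pair, whether the per-frame transition
#' probability trends with an experimental condition level (e.g. catalyst
#' concentration), using Pearson correlation with a Bonferroni-corrected
#' per-test threshold `alpha / (K * (K - 1))` (0.05 / 12 = 0.00417 for
#' K = 4). Also reports the fold-change between the highest and lowest
#' condition.
#'
#' @param A_list List of per-frame transition matrices, one per condition,
#'   all `K x K`.
#' @param levels Numeric condition levels, same length as `A_list`, at least
#'   3 distinct values.
#' @param alpha Familywise significance level (default 0.05).
#' @return Data frame with one row per ordered pair: `from`, `to`, `r`,
#'   `p_value`, `significant`, `fold_change`, plus attribute `threshold`.
#' @export
transition_trend_test <- function(A_list, levels, alpha = 0.05) {
  stopifnot(length(A_list) == length(levels), length(levels) >= 3)
  K <- nrow(A_list[[1]])
  stopifnot(all(vapply(A_list, function(a) all(dim(a) == K), logical(1))))
  n_pairs <- K * (K - 1)
  threshold <- alpha / n_pairs
  i_lo <- which.min(levels)
  i_hi <- which.max(levels)
  rows <- list()
  for (from in seq_len(K)) for (to in seq_len(K)) {
    if (from == to) next
    p_ij <- vapply(A_list, function(a) a[from, to], numeric(1))
    if (stats::sd(p_ij) == 0 || stats::sd(levels) == 0) {
      r <- NA_real_; pval <- NA_real_
    } else {
      ct <- stats::cor.test(levels, p_ij, method = "pearson")
      r <- unname(ct$estimate); pval <- ct$p.value
    }
    fc <- if (p_ij[i_lo] > 0) p_ij[i_hi] / p_ij[i_lo] else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      from = from, to = to, r = r, p_value = pval,
      significant = isTRUE(pval < threshold), fold_change = fc)
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}

#' Normalize a bleaching trace and count bleach steps
#'
#' Affinely rescales a fluorescence intensity trace so the mean pre-bleach
#' intensity is 1 and the mean post-bleach intensity is 0, smooths it with a
#' 3-frame rolling mean, and counts the number of distinct downward intensity
#' levels by a change-point scan (binary segmentation with a BIC-style
#' penalty). A monodisperse particle bleaches in a single step.
#'
#' @param intensity Numeric intensity trace.
#' @param bleach_frame Index of the first post-bleach frame; frames before it
#'   define the pre-bleach mean and frames from it onward the post-bleach
#'   mean.
#' @param smooth_window Rolling-mean window in frames (default 3).
#' @param min_drop Minimum normalized level drop accepted as a step
#'   (default 0.2).
#' @return List with `normalized` (smoothed, normalized trace), `n_steps`,
#'   `levels` (mean of each detected segment), `changepoints`.
#' @export
normalize_bleach_trace <- function(intensity, bleach_frame,
                                   smooth_window = 3L, min_drop = 0.2) {
  n <- length(intensity)
  stopifnot(bleach_frame > 1, bleach_frame <= n)
  pre <- mean(intensity[seq_len(bleach_frame - 1L)])
  post <- mean(intensity[bleach_frame:n])
  if (!is.finite(pre) || !is.finite(post) || pre == post)
    stop("degenerate trace: pre- and post-bleach means are equal")
  z <- (intensity - post) / (pre - post)
  sm <- as.numeric(stats::filter(z, rep(1 / smooth_window, smooth_window),
                                 sides = 2))
  # shrinking windows at the edges
  half <- smooth_window %/% 2
  for (i in which(is.na(sm))) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    sm[i] <- mean(z[lo:hi])
  }
  # step counting runs on the unsmoothed normalized trace: the rolling mean
  # is for plotting and would turn each step into a ramp of its own levels
  cps <- binary_segmentation(z)
  bounds <- c(0L, sort(cps), n)
  seg_means <- vapply(seq_len(length(bounds) - 1L), function(k) {
    mean(z[(bounds[k] + 1L):bounds[k + 1L]])
  }, numeric(1))
  drops <- -diff(seg_means)
  n_steps <- sum(drops >= min_drop)
  list(normalized = sm, n_steps = n_steps, levels = seg_means,
       changepoints = sort(cps))
}

# binary segmentation on the mean: split while the BIC improves
binary_segmentation <- function(x, min_seg = 3L, max_depth = 6L) {
  n <- length(x)
  sigma2 <- max(stats::var(diff(x)) / 2, 1e-12)
  penalty <- 3 * log(n) * sigma2
  split_rss_gain <- function(lo, hi) {
    seg <- x[lo:hi]
    m <- length(seg)
    if (m < 2L * min_seg) return(NULL)
    tot <- sum((seg - mean(seg))^2)
    cs <- cumsum(seg); css <- cumsum(seg^2)
    best_gain <- -Inf; best_k <- NA_integer_
    for (k in min_seg:(m - min_seg)) {
      rss_l <- css[k] - cs[k]^2 / k
      rss_r <- (css[m] - css[k]) - (cs[m] - cs[k])^2 / (m - k)
      gain <- tot - rss_l - rss_r
      if (gain > best_gain) { best_gain <- gain; best_k <- k }
    }
    if (best_gain > penalty) lo + best_k - 1L else NULL
  }
  cps <- integer(0)
  recurse <- function(lo, hi, depth) {
    if (depth > max_depth) return()
    k <- split_rss_gain(lo, hi)
    if (is.null(k)) return()
    cps <<- c(cps, k)
    recurse(lo, k, depth + 1L)
    recurse(k + 1L, hi, depth + 1L)
  }
  recurse(1L, n, 1L)
  cps
}
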