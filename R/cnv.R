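#' Per-bin log2 copy-number ratios
#'
#' Library-size normalizes tumor and normal binned read counts (each vector
#' scaled to its total, so depths are comparable as read frequencies),
#' computes the per-bin log2 tumor/normal ratio, and centers the ratios so
#' their median is exactly zero. Bins with a zero count on either side are
#' masked (NA ratio) and ignored downstream.
#'
#' @param tumor either a combined data frame (chrom, bin, bin_start,
#'   tumor_count, normal_count) as produced by [simulate_cnv_counts()], or a
#'   data frame with chrom, bin, bin_start, count when `normal` is given.
#' @param normal optional normal-count data frame on the same bin grid.
#' @return bin profile data frame: chrom, bin, bin_start, tumor_count,
#'   normal_count, log2_ratio (median-centered, NA where masked).
#' @export
compute_ratios <- function(tumor, normal = NULL) {
  if (is.null(normal)) {
    need <- c("chrom", "bin", "bin_start", "tumor_count", "normal_count")
    if (!all(need %in% names(tumor)))
      stop("combined count table needs columns: ",
           paste(need, collapse = ", "))
    counts <- tumor
  } else {
    if (!identical(tumor[c("chrom", "bin", "bin_start")],
                   normal[c("chrom", "bin", "bin_start")]))
      stop("tumor and normal bin grids differ")
    counts <- tumor[c("chrom", "bin", "bin_start")]
    counts$tumor_count <- tumor$count
    counts$normal_count <- normal$count
  }
  if (any(counts$tumor_count < 0) || any(counts$normal_count < 0))
    stop("bin counts must be non-negative")
  tf <- counts$tumor_count / sum(counts$tumor_count)
  nf <- counts$normal_count / sum(counts$normal_count)
  ratio <- ifelse(counts$tumor_count > 0 & counts$normal_count > 0,
                  log2(tf / nf), NA_real_)
  ratio <- ratio - stats::median(ratio, na.rm = TRUE)
  counts$log2_ratio <- ratio
  counts
}

# Candidate-pair machinery for the circular-binary-segmentation-style test:
# the statistic for a candidate segment (i..j) inside a window of length n is
# |mean(in) - mean(out)| / sqrt(1/k + 1/(n-k)), equivalently
# |sum of centered values in (i..j)| * sqrt(n / (k (n-k))). The maximum is
# taken over all pairs with min_len <= k <= n - min_len; pairs touching the
# window edge reduce to plain two-way splits. The weight matrix depends only
# on n, so it is precomputed once per window and shared by all permutations.
pair_prep <- function(n, min_len) {
  b <- 0:n
  k <- outer(b, b, "-")           # segment length for boundaries (col, row)
  w <- suppressWarnings(sqrt(n / (k * (n - k))))
  w[!(k >= min_len & k <= n - min_len)] <- NA_real_
  w
}

# Maximizing pair for one vector; returns NULL when no pair is admissible.
pair_stat <- function(x, w) {
  n <- length(x)
  cz <- c(0, cumsum(x - mean(x)))
  d <- abs(outer(cz, cz, "-")) * w
  m <- which.max(d)
  if (!length(m)) return(NULL)
  u <- (m - 1L) %% (n + 1L) + 1L   # row: end boundary + 1
  v <- (m - 1L) %/% (n + 1L) + 1L  # col: start boundary + 1
  list(i = v, j = u - 1L, stat = d[m])
}

#' Segment a copy-number profile by recursive binary splitting
#'
#' Changepoint detection on the centered log2 ratios, one chromosome at a
#' time: the candidate boundary maximizing the two-segment mean-difference
#' statistic is accepted when its max-statistic permutation p-value falls
#' below `alpha`, and the two halves are then segmented recursively.
#' Masked (NA-ratio) bins are skipped; segments are reported on the original
#' bin indices and cover all unmasked bins without overlap. Permutations
#' draw from the current RNG stream, so seed before calling for
#' reproducibility.
#'
#' @param profile bin profile from [compute_ratios()].
#' @param alpha significance level for accepting a split (default 0.01).
#' @param B permutations per split test (default 1000).
#' @param min_len minimum segment length in bins (default 3).
#' @return segment data frame: chrom, start_bin, end_bin, n_bins,
#'   mean_ratio, state (NA until [call_states()]).
#' @export
segment_ratios <- function(profile, alpha = 0.01, B = 1000L, min_len = 3L) {
  stopifnot(is.data.frame(profile), "log2_ratio" %in% names(profile))
  out <- list()
  for (chrom in unique(profile$chrom)) {
    p <- profile[profile$chrom == chrom & !is.na(profile$log2_ratio), ,
                 drop = FALSE]
    if (!nrow(p)) next
    x <- p$log2_ratio
    bins <- p$bin
    segs <- segment_recurse(x, alpha, B, min_len)
    for (s in segs) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom,
        start_bin = bins[s[1L]],
        end_bin = bins[s[2L]],
        n_bins = s[2L] - s[1L] + 1L,
        mean_ratio = mean(x[s[1L]:s[2L]]),
        state = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start_bin = integer(0),
                      end_bin = integer(0), n_bins = integer(0),
                      mean_ratio = numeric(0), state = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Recursive splitter on indices of x; returns list of c(start, end) pairs.
# The permutation loop stops as soon as the exceedance count rules out
# p < alpha (the decision is exact; only wasted permutations are skipped).
segment_recurse <- function(x, alpha, B, min_len) {
  n <- length(x)
  if (n < 2L * min_len) return(list(c(1L, n)))
  w <- pair_prep(n, min_len)
  obs <- pair_stat(x, w)
  if (is.null(obs)) return(list(c(1L, n)))
  exceed_max <- floor(alpha * (B + 1L) - 1 - 1e-9)
  if (exceed_max < 0) return(list(c(1L, n)))
  exceed <- 0L
  for (b in seq_len(B)) {
    if (pair_stat(sample(x), w)$stat >= obs$stat) {
      exceed <- exceed + 1L
      if (exceed > exceed_max) return(list(c(1L, n)))
    }
  }
  i <- obs$i; j <- obs$j
  parts <- list()
  if (i > 1L) parts <- c(parts, lapply(
    segment_recurse(x[1:(i - 1L)], alpha, B, min_len), identity))
  mid <- segment_recurse(x[i:j], alpha, B, min_len)
  parts <- c(parts, lapply(mid, function(s) s + i - 1L))
  if (j < n) {
    right <- segment_recurse(x[(j + 1L):n], alpha, B, min_len)
    parts <- c(parts, lapply(right, function(s) s + j))
  }
  parts
}

#' Call gain/loss/neutral states with a k-standard-deviation rule
#'
#' The residual spread is estimated from bin-level deviations around their
#' segment means — robustly via the median absolute deviation (scaled by
#' 1.4826) by default, or the plain standard deviation. A segment is a gain
#' when its mean exceeds `+k` estimated SDs, a loss below `-k` SDs, neutral
#' otherwise (k = 2 by default, the two-standard-deviation threshold).
#'
#' @param segments output of [segment_ratios()].
#' @param profile the bin profile the segments were fitted on.
#' @param k state threshold in residual SD units.
#' @param sd_method "mad" (default) or "sd".
#' @return `segments` with the state column filled.
#' @export
call_states <- function(segments, profile, k = 2,
                        sd_method = c("mad", "sd")) {
  sd_method <- match.arg(sd_method)
  if (!nrow(segments)) return(segments)
  resid <- numeric(0)
  for (i in seq_len(nrow(segments))) {
    sel <- profile$chrom == segments$chrom[i] &
      profile$bin >= segments$start_bin[i] &
      profile$bin <= segments$end_bin[i] &
      !is.na(profile$log2_ratio)
    resid <- c(resid, profile$log2_ratio[sel] - segments$mean_ratio[i])
  }
  s <- if (sd_method == "mad") stats::mad(resid) else stats::sd(resid)
  segments$state <- ifelse(segments$mean_ratio > k * s, "gain",
                           ifelse(segments$mean_ratio < -k * s, "loss",
                                  "neutral"))
  segments
}

#' Read-depth CNV detection, end to end
#'
#' Convenience wrapper: [compute_ratios()], [segment_ratios()],
#' [call_states()].
#'
#' @param counts combined bin-count table (see [compute_ratios()]).
#' @param alpha,B,min_len segmentation controls.
#' @param k,sd_method state-calling controls.
#' @return list with `profile` and `segments`.
#' @export
detect_cnv <- function(counts, alpha = 0.01, B = 1000L, min_len = 3L,
                       k = 2, sd_method = "mad") {
  profile <- compute_ratios(counts)
  segments <- segment_ratios(profile, alpha = alpha, B = B,
                             min_len = min_len)
  segments <- call_states(segments, profile, k = k, sd_method = sd_method)
  list(profile = profile, segments = segments)
}
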