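# Millisecond-resolution gaze-occupancy analysis: per-subject occupancy
# proportions, pointwise t statistics, cluster formation, and family-wise
# correction by the maximum cluster-mass permutation distribution.

#' Gaze-occupancy proportions over trial time
#'
#' For each subject and each millisecond up to `horizon_ms`, the proportion
#' of that subject's trials (in the given condition) whose gaze is in the
#' Self AOI, the Other AOI, or neither.  By default a trial contributes only
#' while it is still unresolved (before its RT); missed trials contribute
#' throughout.
#'
#' @param trials A trials table.
#' @param fixations A fixations table.
#' @param condition `"HIGH"` or `"LOW"`.
#' @param horizon_ms Analysis horizon in ms (default 837, the point by which
#'   more than half of high-pressure trials have ended).
#' @param include_ended Count trials past their RT as `NEITHER` instead of
#'   dropping them from the denominator.
#' @return A list with class `"occupancy"`: matrices `p_self`, `p_other`,
#'   `p_neither` (subjects x ms, rows named by subject), `n_active`, and the
#'   horizon.  The three proportions sum to 1 wherever any trial is active.
#' @export
occupancy <- function(trials, fixations, condition, horizon_ms = 837,
                      include_ended = FALSE) {
  condition <- match_condition(condition)
  tr <- as.data.frame(trials)
  tr <- tr[toupper(tr$condition) == condition, ]
  if (nrow(tr) == 0) stop("no trials in condition ", condition, call. = FALSE)
  if (max(deadline_s(condition)) * 1000 < horizon_ms &&
      !include_ended) {
    stop("horizon exceeds the condition deadline", call. = FALSE)
  }
  fx <- as.data.frame(fixations)
  key_fx <- paste(fx$subject, fx$trial, sep = ".")
  fx_idx <- split(seq_len(nrow(fx)), key_fx)
  subjects <- unique(tr$subject)
  H <- as.integer(horizon_ms)
  p_self <- p_other <- p_neither <- n_active <-
    matrix(0, length(subjects), H, dimnames = list(subjects, NULL))
  for (si in seq_along(subjects)) {
    rows <- which(tr$subject == subjects[si])
    cnt <- matrix(0, 4, H)  # rows: neither, self, other, active
    for (i in rows) {
      rt_ms <- if (is.na(tr$rt[i])) Inf else tr$rt[i] * 1000
      end_label <- min(H, ceiling(rt_ms))  # AOI labels end at the response
      end_active <- if (include_ended) H else end_label
      if (end_active <= 0) next
      cnt[4, seq_len(end_active)] <- cnt[4, seq_len(end_active)] + 1
      key <- paste(tr$subject[i], tr$trial[i], sep = ".")
      segs <- fx_idx[[key]]
      if (!is.null(segs) && end_label > 0) {
        for (s in segs) {
          a <- max(0, fx$onset_ms[s])
          b <- min(end_label, fx$offset_ms[s])
          if (b > a) {
            r <- match(fx$aoi[s], AOI_LEVELS)  # 1 neither, 2 self, 3 other
            idx <- (floor(a) + 1):ceiling(b)
            idx <- idx[idx <= end_label]
            cnt[r, idx] <- cnt[r, idx] + 1
          }
        }
      }
    }
    # time not covered by any labelled segment counts as NEITHER
    lab <- cnt[1, ] + cnt[2, ] + cnt[3, ]
    cnt[1, ] <- cnt[1, ] + pmax(0, cnt[4, ] - lab)
    act <- pmax(cnt[4, ], 1)
    p_self[si, ] <- cnt[2, ] / act
    p_other[si, ] <- cnt[3, ] / act
    p_neither[si, ] <- cnt[1, ] / act
    n_active[si, ] <- cnt[4, ]
  }
  structure(list(p_self = p_self, p_other = p_other, p_neither = p_neither,
                 n_active = n_active, horizon_ms = H, condition = condition),
            class = "occupancy")
}

#' Self-minus-Other gaze bias series
#'
#' @param occ An [occupancy()] object.
#' @return Matrix (subjects x ms) of `P(gaze in Self) - P(gaze in Other)`.
#' @export
gaze_bias <- function(occ) {
  occ$p_self - occ$p_other
}

# one-sample t statistics for each column of a subjects x time matrix
col_tstat <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  s <- sqrt((colSums(x^2) - n * m^2) / (n - 1))
  t <- m / (s / sqrt(n))
  t[s == 0] <- ifelse(m[s == 0] == 0, 0, sign(m[s == 0]) * Inf)
  list(stat = t, p = 2 * pt(-abs(t), df = n - 1))
}

#' Pointwise gaze-bias statistics
#'
#' `BIAS`: one-sample t across subjects of the Self-minus-Other occupancy
#' bias at each millisecond within one condition.  `CONDITION`: paired t of
#' the bias difference (high minus low pressure).
#'
#' @param occ_high An [occupancy()] object (or bias matrix) for the first
#'   (or only) condition.
#' @param occ_low Second condition for the `CONDITION` contrast.
#' @param contrast `"BIAS"` or `"CONDITION"`.
#' @return A list with `stat` and two-tailed `p` per millisecond, and the
#'   analysed series matrix.
#' @export
pointwise_stat <- function(occ_high, occ_low = NULL,
                           contrast = c("BIAS", "CONDITION")) {
  contrast <- match.arg(contrast)
  b1 <- if (inherits(occ_high, "occupancy")) gaze_bias(occ_high) else occ_high
  if (nrow(b1) < 3) stop("need at least 3 subjects", call. = FALSE)
  series <- if (contrast == "BIAS") {
    b1
  } else {
    b2 <- if (inherits(occ_low, "occupancy")) gaze_bias(occ_low) else occ_low
    stopifnot(!is.null(b2), all(dim(b1) == dim(b2)))
    b1 - b2
  }
  c(col_tstat(series), list(series = series, contrast = contrast))
}

#' Candidate clusters of adjacent significant time points
#'
#' Maximal runs of at least `min_len` adjacent time points with `p < alpha`
#' and a common statistic sign; the cluster mass is the summed `|stat|`.
#'
#' @param p Pointwise two-tailed p values.
#' @param stat Pointwise statistics (same length).
#' @param alpha Cluster-forming threshold (default 0.01).
#' @param min_len Minimum run length (default 2).
#' @return A data.frame with `start_ms`, `end_ms` (0-based, end exclusive),
#'   `length`, `mass`, `sign`.
#' @export
form_clusters <- function(p, stat, alpha = 0.01, min_len = 2) {
  stopifnot(length(p) == length(stat))
  sig <- !is.na(p) & p < alpha
  lab <- ifelse(sig, sign(stat), 0)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0 & r$lengths >= min_len
  data.frame(
    start_ms = starts[keep] - 1,
    end_ms = ends[keep],
    length = r$lengths[keep],
    mass = vapply(which(keep), function(i) {
      sum(abs(stat[starts[i]:ends[i]]))
    }, numeric(1)),
    sign = r$values[keep]
  )
}

# max cluster mass of one series (helper shared with the permutations)
max_cluster_mass <- function(p, stat, alpha, min_len) {
  cl <- form_clusters(p, stat, alpha, min_len)
  if (nrow(cl) == 0) 0 else max(cl$mass)
}

#' Cluster-mass permutation test of gaze-bias series
#'
#' Family-wise corrected test of the pointwise bias (or condition-difference)
#' series using the maximum cluster-mass statistic.  The null distribution is
#' built by sign-flipping each subject's whole series (`BIAS`; equivalently,
#' swapping condition labels within subject for `CONDITION`, whose
#' differencing reduces to the same sign flip).  An observed cluster is
#' significant when its mass exceeds the 95th percentile of the permuted
#' maxima; reported p values are permutation p values for each cluster mass.
#'
#' @inheritParams pointwise_stat
#' @param alpha Cluster-forming threshold on pointwise p values (default
#'   0.01, two-tailed).
#' @param min_len Minimum cluster length in ms (default 2).
#' @param n_perm Number of permutations (default 1000).
#' @return A list with class `"cluster_result"`: `clusters` (with corrected
#'   `p` and `significant`), `threshold` (95th percentile of the null
#'   maxima), `tmax_null`, the pointwise `stat`/`p` series, `n_perm`.
#' @export
permutation_tmax <- function(occ_high, occ_low = NULL,
                             contrast = c("BIAS", "CONDITION"),
                             alpha = 0.01, min_len = 2, n_perm = 1000) {
  contrast <- match.arg(contrast)
  if (n_perm < 100) {
    warning("fewer than 100 permutations gives a coarse null", call. = FALSE)
  }
  pw <- pointwise_stat(occ_high, occ_low, contrast)
  x <- pw$series
  n <- nrow(x)
  H <- ncol(x)
  obs <- form_clusters(pw$p, pw$stat, alpha, min_len)

  # permutation t statistics: sign flips leave column sums of squares fixed
  sumsq <- colSums(x^2)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  means <- signs %*% x / n
  vars <- sweep(-n * means^2, 2, sumsq, "+") / (n - 1)
  tmat <- means / sqrt(vars / n)
  tmat[!is.finite(tmat)] <- 0
  pmat <- 2 * pt(-abs(tmat), df = n - 1)
  tmax_null <- vapply(seq_len(n_perm), function(i) {
    max_cluster_mass(pmat[i, ], tmat[i, ], alpha, min_len)
  }, numeric(1))
  threshold <- quantile(tmax_null, 0.95, names = FALSE)
  if (nrow(obs) > 0) {
    obs$p <- vapply(obs$mass, function(m) {
      (1 + sum(tmax_null >= m)) / (n_perm + 1)
    }, numeric(1))
    obs$significant <- obs$mass > threshold
  } else {
    obs$p <- numeric(0)
    obs$significant <- logical(0)
  }
  structure(list(clusters = obs, threshold = threshold,
                 tmax_null = tmax_null, stat = pw$stat, p = pw$p,
                 alpha = alpha, min_len = min_len, n_perm = n_perm,
                 contrast = contrast),
            class = "cluster_result")
}

#' Early gaze bias of one trial
#'
#' Signed Self-minus-Other dwell time over the first `window_ms` of the
#' trial (or up to the RT when the response came earlier), normalised by the
#' analysed duration; bounded in `[-1, 1]`.
#'
#' @param timeline A gaze timeline.
#' @param rt Reaction time in seconds (`NA` for missed trials, which use the
#'   full window).
#' @param window_ms Analysis window in ms (default 286).
#' @return The proportion bias, or `NA` (with a warning) when the analysed
#'   duration is zero.
#' @export
early_gaze_bias <- function(timeline, rt = NA, window_ms = 286) {
  w <- if (is.na(rt)) window_ms else min(window_ms, rt * 1000)
  if (w <= 0) {
    warning("zero analysed duration; trial skipped", call. = FALSE)
    return(NA_real_)
  }
  tl <- as.data.frame(timeline)
  dwell <- function(aoi) {
    seg <- tl[tl$aoi == aoi, , drop = FALSE]
    if (nrow(seg) == 0) return(0)
    sum(pmax(0, pmin(seg$offset, w) - pmax(seg$onset, 0)))
  }
  (dwell("SELF") - dwell("OTHER")) / w
}

#' Per-subject early gaze biases
#'
#' Trial-level [early_gaze_bias()] averaged within subject for one
#' condition.
#'
#' @param trials A trials table.
#' @param fixations A fixations table.
#' @param condition `"HIGH"` or `"LOW"`.
#' @param window_ms Analysis window in ms.
#' @return Named numeric vector of mean biases per subject.
#' @export
early_gaze_bias_by_subject <- function(trials, fixations, condition,
                                       window_ms = 286) {
  tr <- as.data.frame(trials)
  tr <- tr[toupper(tr$condition) == match_condition(condition), ]
  tls <- timelines_from_fixations(fixations, tr)
  vals <- vapply(seq_len(nrow(tr)), function(i) {
    early_gaze_bias(tls[[i]], tr$rt[i], window_ms)
  }, numeric(1))
  tapply(vals, tr$subject, mean, na.rm = TRUE)
}

#' Brown-Forsythe test of equal variances
#'
#' One-way ANOVA on absolute deviations from the group medians; robust to
#' non-normality and invariant to group location shifts.
#'
#' @param groups A list of numeric vectors (one per group), each with at
#'   least 2 values.
#' @return A list with `statistic` (F), `df`, and `p.value`.
#' @examples
#' brown_forsythe(list(rnorm(30), rnorm(30, sd = 3)))
#' @export
brown_forsythe <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  z <- unlist(lapply(groups, function(x) abs(x - median(x))))
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  fit <- oneway.test(z ~ g, var.equal = TRUE)
  list(statistic = unname(fit$statistic),
       df = unname(fit$parameter),
       p.value = fit$p.value)
}
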