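#' Normalized variance (squared coefficient of variation)
#'
#' The population noise measure NV = sigma^2 / mu^2, computed with the
#' population (divide-by-n) variance: NV is a distribution functional and
#' is typically evaluated on large cell populations.
#'
#' @param values numeric vector (n >= 2, mean != 0).
#' @return NV, dimensionless.
#' @export
normalized_variance <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2)
    msim_stop("need at least two values", "insufficient_data")
  mu <- mean(values)
  if (mu == 0) msim_stop("NV undefined for zero mean", "undefined_nv")
  v <- mean((values - mu)^2)
  v / mu^2
}

#' Summary statistics of an expression distribution
#'
#' @param values numeric vector.
#' @return List with `mean`, `variance` (population), `nv`, `median`, `n`;
#'   `nv` is `NA` when the mean is zero.
#' @export
stat_summary <- function(values) {
  mu <- mean(values)
  v <- mean((values - mu)^2)
  list(mean = mu, variance = v,
       nv = if (mu != 0) v / mu^2 else NA_real_,
       median = median(values), n = length(values))
}

#' Autocorrelation function of a regularly sampled trace
#'
#' Biased single-mean estimator standard in fluctuation analysis:
#' `r(k) = sum_{t=1}^{n-k} (x_t - xbar)(x_{t+k} - xbar) / sum (x_t - xbar)^2`
#' with the global mean `xbar`; guarantees `r(0) = 1` and `|r| <= 1`.
#'
#' @param values numeric vector sampled on a regular grid (>= 10 points).
#' @param dt grid spacing, min.
#' @param max_lag largest lag, min (must be smaller than the trace span).
#' @return An object of class `acf_result`: list with `lags` (min), `acf`,
#'   `tau_half` (min; `NA` until [tau_half()] is applied), `censored`,
#'   `n_points`.
#' @export
autocorrelation <- function(values, dt = 10, max_lag = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 10) msim_stop("need at least 10 grid points", "insufficient_data")
  if (is.null(max_lag)) max_lag <- (n - 1) * dt / 2
  if (max_lag >= n * dt)
    msim_stop("max_lag must be smaller than the trace span", "insufficient_data")
  xbar <- mean(values)
  xc <- values - xbar
  denom <- sum(xc^2)
  if (denom == 0) msim_stop("ACF undefined for a constant series", "undefined_acf")
  kmax <- min(n - 1, floor(max_lag / dt))
  r <- vapply(0:kmax, function(k) {
    sum(xc[seq_len(n - k)] * xc[seq_len(n - k) + k]) / denom
  }, numeric(1))
  structure(list(lags = (0:kmax) * dt, acf = r, tau_half = NA_real_,
                 censored = NA, n_points = n),
            class = "acf_result")
}

#' Half-decay time of an autocorrelation function
#'
#' The lag at which the ACF first drops to 0.5, linearly interpolated
#' between the bracketing lags — the operational "cellular memory"
#' timescale. When the ACF never reaches 0.5 within the computed window the
#' value is right-censored at the largest lag (`censored = TRUE`).
#'
#' @param acf an `acf_result` from [autocorrelation()], or a list with
#'   `lags` and `acf`.
#' @return The `acf_result` with `tau_half` (min) and `censored` filled in.
#' @export
tau_half <- function(acf) {
  lags <- acf$lags; r <- acf$acf
  below <- which(r < 0.5)
  if (length(below) == 0) {
    acf$tau_half <- max(lags)
    acf$censored <- TRUE
    return(acf)
  }
  i <- below[1]
  if (i == 1) {
    # below 0.5 already at the first lag (only possible at lag 0 for a
    # degenerate input); report the first lag
    acf$tau_half <- lags[1]
  } else {
    r0 <- r[i - 1]; r1 <- r[i]
    acf$tau_half <- lags[i - 1] + (r0 - 0.5) / (r0 - r1) * (lags[i] - lags[i - 1])
  }
  acf$censored <- FALSE
  acf
}

#' Fraction of cells above an expression threshold
#'
#' @param values numeric vector of per-cell levels.
#' @param threshold positivity threshold; cells strictly above count as
#'   positive.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_positive <- function(values, threshold) {
  if (length(values) < 1) msim_stop("need at least one value", "insufficient_data")
  mean(values > threshold)
}

#' Quadrant fractions of a two-channel snapshot
#'
#' Classifies every cell as positive/negative in each channel (strictly
#' above the channel threshold = positive) and returns the four joint
#' fractions, in the order double-positive, A-only, B-only,
#' double-negative.
#'
#' @param a,b per-cell levels in the two channels.
#' @param threshold_a,threshold_b channel positivity thresholds.
#' @return Named numeric vector `c(pp, pn, np, nn)` summing to 1.
#' @export
quadrant_fractions <- function(a, b, threshold_a, threshold_b) {
  if (length(a) != length(b) || length(a) < 1)
    msim_stop("channels must be equal-length and non-empty", "insufficient_data")
  ap <- a > threshold_a; bp <- b > threshold_b
  c(pp = mean(ap & bp), pn = mean(ap & !bp),
    np = mean(!ap & bp), nn = mean(!ap & !bp))
}

#' Fit an exponential-decay half-life
#'
#' Least-squares fit of `log(values)` against time; the half-life is
#' `-log(2) / slope`. Used to validate that printed reporter half-lives are
#' recoverable from decay traces.
#'
#' @param times time points, min (>= 3).
#' @param values strictly positive decaying levels.
#' @return Half-life in minutes.
#' @export
fit_half_life <- function(times, values) {
  if (length(times) < 3 || length(times) != length(values))
    msim_stop("need >= 3 paired points", "insufficient_data")
  if (any(values <= 0))
    msim_stop("values must be strictly positive", "domain")
  slope <- coef(lm(log(values) ~ times))[[2]]
  if (slope >= -1e-12) msim_stop("no decay: non-negative slope", "no_decay")
  -log(2) / slope
}

#' Pearson correlation between paired per-cell statistics
#'
#' E.g. the correlation between the ACF half-decay times of the two
#' reporters across cells, used to detect shared (extrinsic) degradation.
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @return Pearson correlation in `[-1, 1]`.
#' @export
reporter_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    msim_stop("need >= 3 pairs", "insufficient_data")
  if (var(x) == 0 || var(y) == 0)
    msim_stop("correlation undefined: zero variance", "undefined_correlation")
  cor(x, y)
}

#' Per-line fluctuation statistics of a tracking table
#'
#' Computes, for one followed cell line per founder tree in a time-lapse
#' tracking table (as produced by [generate_timelapse_table()]), the mean
#' level, NV, ACF half-decay time and its censoring flag, per channel —
#' the per-cell analysis applied to tracked movie lines. Within each
#' `root_id` tree the followed line starts at the founder and descends to
#' the lowest-numbered daughter at every division (tracking software
#' follows one of the two daughters; the choice is arbitrary).
#'
#' Lines shorter than `min_points` frames are skipped.
#'
#' @param table tracking-table data frame with columns `root_id`,
#'   `cell_id`, `parent_id`, `time_min`, `total_A`, `total_B`.
#' @param dt frame spacing, min.
#' @param max_lag largest ACF lag, min (default half the trace span).
#' @param min_points minimum frames per line (default 30).
#' @return Data frame, one row per line: `line_id`, and per channel
#'   `mean_*`, `nv_*`, `tau_half_*`, `censored_*`.
#' @export
analyze_tracking <- function(table, dt = 10, max_lag = NULL, min_points = 30) {
  if (!"root_id" %in% names(table)) table$root_id <- 1L
  out <- lapply(split(table, table$root_id), function(tree) {
    ids <- unique(tree$cell_id)
    cur <- ids[is.na(tree$parent_id[match(ids, tree$cell_id)])][1]
    path <- cur
    repeat {
      kids <- ids[!is.na(tree$parent_id[match(ids, tree$cell_id)]) &
                  tree$parent_id[match(ids, tree$cell_id)] == cur]
      if (length(kids) == 0) break
      cur <- min(kids)
      path <- c(path, cur)
    }
    d <- tree[tree$cell_id %in% path, ]
    d <- d[order(d$time_min), ]
    d <- d[!duplicated(d$time_min), ]
    if (nrow(d) < min_points) return(NULL)
    one <- function(v) {
      s <- stat_summary(v)
      ar <- tau_half(autocorrelation(v, dt = dt, max_lag = max_lag))
      c(mean = s$mean, nv = s$nv, tau_half = ar$tau_half,
        censored = as.numeric(ar$censored))
    }
    a <- one(d$total_A); b <- one(d$total_B)
    data.frame(line_id = d$root_id[1],
               mean_A = a["mean"], nv_A = a["nv"], tau_half_A = a["tau_half"],
               censored_A = a["censored"] == 1,
               mean_B = b["mean"], nv_B = b["nv"], tau_half_B = b["tau_half"],
               censored_B = b["censored"] == 1)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
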