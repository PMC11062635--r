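#' Plate-reader growth curve
#'
#' @param times hours, strictly increasing, >= 4 points (three consecutive
#'   interval rates are needed downstream).
#' @param od OD600 values, positive, same length as `times`.
#' @param replicate,lineage ids carried through to estimates.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(times, od, replicate = NA_character_,
                         lineage = NA_character_) {
  times <- as.numeric(times); od <- as.numeric(od)
  if (length(times) != length(od)) stop("times and od lengths differ")
  if (length(times) < 4) stop("growth curve needs at least 4 points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(od)) || any(od <= 0)) stop("od values must be positive")
  structure(list(times = times, od = od, replicate = replicate,
                 lineage = lineage), class = "growth_curve")
}

#' Per-interval exponential rates
#'
#' For consecutive measurements (t_i, C_i), r_i = ln(C_{i+1}/C_i) /
#' (t_{i+1} - t_i). These interval rates are the raw material for the
#' windowed growth-rate rule.
#'
#' @param curve a [growth_curve()].
#' @return numeric vector of length `n_points - 1`.
#' @export
#' @examples
#' cv <- growth_curve(c(0, .5, 1, 1.5), c(.01, .02, .04, .08))
#' rate_segments(cv)  # all log(2)/0.5
rate_segments <- function(curve) {
  stopifnot(inherits(curve, "growth_curve"))
  diff(log(curve$od)) / diff(curve$times)
}

#' Windowed growth-rate selection
#'
#' Scans all windows of three consecutive interval rates. Among the windows
#' whose coefficient of variation (SD/|mean|) is at most `cv_max`, the one
#' with the largest mean wins; the growth rate is that window's mean. If no
#' window passes the CV filter, the fallback score mean - lambda * SD is
#' maximized instead. Ties go to the earliest window.
#'
#' @param rates numeric vector of interval rates (>= 3).
#' @param cv_max CV threshold for "minor variance" (default 0.2).
#' @param lambda fallback penalty weight (default 1).
#' @return list with `rate` (the window mean) and `rate_window` (index triple
#'   into `rates`).
#' @export
select_rate_window <- function(rates, cv_max = 0.2, lambda = 1) {
  if (length(rates) < 3) stop("need at least 3 interval rates")
  n <- length(rates) - 2
  means <- sds <- numeric(n)
  for (i in seq_len(n)) {
    w <- rates[i:(i + 2)]
    means[i] <- mean(w)
    sds[i] <- stats::sd(w)
  }
  cv <- ifelse(means == 0, Inf, sds / abs(means))
  pass <- which(cv <= cv_max)
  if (length(pass) > 0) {
    best <- pass[which.max(means[pass])]
  } else {
    best <- which.max(means - lambda * sds)
  }
  list(rate = means[best], rate_window = best:(best + 2))
}

#' Robust carrying capacity
#'
#' Mean of the top-k OD values (default k = 3), robust to a single spiked
#' read while tracking the saturated density.
#'
#' @param curve a [growth_curve()].
#' @param k number of top values averaged.
#' @return OD600 value.
#' @export
carrying_capacity <- function(curve, k = 3) {
  stopifnot(inherits(curve, "growth_curve"))
  k <- min(k, length(curve$od))
  mean(sort(curve$od, decreasing = TRUE)[seq_len(k)])
}

#' Growth estimate from one curve
#'
#' Combines [rate_segments()], [select_rate_window()] and
#' [carrying_capacity()] into a one-row summary.
#'
#' @inheritParams select_rate_window
#' @param curve a [growth_curve()].
#' @return object of class `growth_estimate`: rate, rate_window,
#'   carrying_capacity, replicate, lineage.
#' @export
estimate_growth <- function(curve, cv_max = 0.2, lambda = 1) {
  sel <- select_rate_window(rate_segments(curve), cv_max, lambda)
  structure(list(rate = sel$rate, rate_window = sel$rate_window,
                 carrying_capacity = carrying_capacity(curve),
                 replicate = curve$replicate, lineage = curve$lineage),
            class = "growth_estimate")
}

#' @export
print.growth_estimate <- function(x, ...) {
  cat(sprintf("growth_estimate: r = %.4f /h (window %d-%d), K = %.4f OD600\n",
              x$rate, x$rate_window[1], x$rate_window[3],
              x$carrying_capacity))
  invisible(x)
}

#' Generations and daily rates from a serial-transfer log
#'
#' Per day, generations G = log2(Nt / N0) and rate mu = ln(Nt / N0) / dt,
#' where N0 and Nt are the ODs just after dilution and at transfer.
#'
#' @param log a `transfer_log` data.frame (columns day, od_start, od_end,
#'   interval_h at minimum).
#' @return data.frame: day, generations, cumulative_generations, mu.
#' @export
#' @examples
#' tl <- data.frame(day = 1, od_start = 1e-5, od_end = 0.1, interval_h = 24)
#' generations(tl)  # log2(1e4) = 13.29 generations
generations <- function(log) {
  req <- c("day", "od_start", "od_end", "interval_h")
  miss <- setdiff(req, names(log))
  if (length(miss) > 0)
    stop("transfer log lacks columns: ", paste(miss, collapse = ", "))
  if (any(log$od_start <= 0) || any(log$od_end <= 0))
    stop("transfer-log ODs must be positive")
  g <- log2(log$od_end / log$od_start)
  mu <- log(log$od_end / log$od_start) / log$interval_h
  data.frame(day = log$day, generations = g,
             cumulative_generations = cumsum(g), mu = mu)
}

#' Nonparametric growth-statistic comparisons
#'
#' Two-sided Mann-Whitney U between two groups, and (when `paired` vectors
#' are supplied) Spearman rank correlation — the comparisons used for
#' rate-vs-rate and rate-vs-capacity summaries.
#'
#' @param a,b numeric vectors (each >= 2 values for the U test).
#' @param paired optional list(x =, y =) of equal-length vectors for the
#'   Spearman correlation.
#' @return list with `u` (U statistic for a over b), `p_u`, and when paired
#'   data given, `rho` and `p_rho`.
#' @export
compare_growth <- function(a, b, paired = NULL) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  out <- list(u = unname(wt$statistic), p_u = wt$p.value)
  if (!is.null(paired)) {
    if (length(paired$x) != length(paired$y))
      stop("paired vectors must have equal length")
    ct <- suppressWarnings(
      stats::cor.test(paired$x, paired$y, method = "spearman"))
    out$rho <- unname(ct$estimate)
    out$p_rho <- ct$p.value
  }
  out
}

#' Read a wide plate-reader CSV
#'
#' Expected format: first column `time_min`, one column per well.
#'
#' @param path CSV path.
#' @param lineages optional named map well -> lineage id.
#' @return list of [growth_curve()], one per well column.
#' @export
read_plate_csv <- function(path, lineages = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_min") stop("first column must be time_min")
  times <- df$time_min / 60
  wells <- names(df)[-1]
  lapply(wells, function(w) {
    lin <- if (!is.null(lineages) && w %in% names(lineages)) lineages[[w]]
           else w
    growth_curve(times, df[[w]], replicate = w, lineage = lin)
  })
}

#' Read a serial-transfer TSV
#' @param path TSV with columns day, dilution, od_start, od_end, interval_h.
#' @return a `transfer_log` data.frame.
#' @export
read_transfer_log <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  class(df) <- c("transfer_log", "data.frame")
  df
}
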