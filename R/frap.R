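# FRAP (fluorescence recovery after photobleaching) normalization and
# single-exponential recovery fitting.

#' Construct a four-ROI FRAP trace
#'
#' @param time_s Acquisition times, seconds (nonuniform allowed; the
#'   standard protocol records 0.5-s intervals for the first 40 post-bleach
#'   frames, then 1-s intervals).
#' @param bleached_fls,unbleached_fls Structure ROI intensity series.
#' @param bleached_bg,unbleached_bg Paired background ROI series.
#' @return A `frap_trace` data.frame.
#' @export
frap_trace <- function(time_s, bleached_fls, unbleached_fls,
                       bleached_bg, unbleached_bg) {
  n <- length(time_s)
  stopifnot(length(bleached_fls) == n, length(unbleached_fls) == n,
            length(bleached_bg) == n, length(unbleached_bg) == n)
  structure(
    data.frame(time_s = time_s, bleached_fls = bleached_fls,
               unbleached_fls = unbleached_fls, bleached_bg = bleached_bg,
               unbleached_bg = unbleached_bg),
    class = c("frap_trace", "data.frame")
  )
}

#' Detect the bleach frame
#'
#' The bleach frame is the frame after the largest frame-to-frame drop in
#' intensity, ties broken to the earliest occurrence.
#'
#' @param series Intensity series (>= 3 frames).
#' @return Integer index (1-based) of the first post-bleach frame.
#' @export
detect_bleach_frame <- function(series) {
  stopifnot(length(series) >= 3)
  drops <- series[-length(series)] - series[-1]
  if (max(drops) <= 0) stop("no intensity drop found: series never decreases")
  which.max(drops) + 1L
}

#' Normalize a FRAP trace
#'
#' Standard full-scale normalization: (1) subtract each structure ROI's
#' paired background; (2) correct for acquisition photobleaching by
#' dividing the bleached series by the unbleached series relative to its
#' own prebleach mean; (3) scale so the prebleach mean is 1; (4) shift and
#' rescale so the bleach-frame value is exactly 0 while the prebleach
#' level stays 1. The result is invariant to affine gain/offset changes in
#' the raw intensities.
#'
#' @param trace A [frap_trace()].
#' @param bleach_frame Optional known bleach frame; detected via
#'   [detect_bleach_frame()] when `NULL`.
#' @return List with `time_s`, `normalized`, `bleach_frame`,
#'   `post_time_s` (seconds since the bleach frame, post-bleach only),
#'   `post_normalized`.
#' @export
normalize_frap <- function(trace, bleach_frame = NULL) {
  stopifnot(inherits(trace, "frap_trace"))
  bl <- trace$bleached_fls - trace$bleached_bg
  un <- trace$unbleached_fls - trace$unbleached_bg
  if (is.null(bleach_frame)) bleach_frame <- detect_bleach_frame(bl)
  if (bleach_frame < 2) stop("no prebleach frames before the bleach frame")
  pre <- seq_len(bleach_frame - 1)
  if (any(un <= 0))
    stop("unbleached ROI non-positive after background subtraction")
  acq <- un / mean(un[pre])                 # acquisition-bleach factor
  y <- bl / acq
  y <- y / mean(y[pre])                     # prebleach mean -> 1
  y0 <- y[bleach_frame]
  if (y0 >= 1) stop("bleach frame not below prebleach level")
  y <- (y - y0) / (1 - y0)                  # bleach frame -> 0, prebleach -> 1
  post <- bleach_frame:nrow(trace)
  list(time_s = trace$time_s, normalized = y, bleach_frame = bleach_frame,
       post_time_s = trace$time_s[post] - trace$time_s[bleach_frame],
       post_normalized = y[post])
}

#' Fit the post-bleach recovery curve
#'
#' Least-squares fit of \eqn{A (1 - e^{-k t})} to the normalized
#' post-bleach frames, in real time units (never frame indices, since
#' sampling is nonuniform). Half-time is \eqn{\ln 2 / k}; percent recovery
#' is \eqn{100 A}. A flat series (no recovery) is flagged with an
#' undefined half-time.
#'
#' @param normalized Output of [normalize_frap()], or a list with
#'   `post_time_s` and `post_normalized`.
#' @return A `frap_fit` list: `rate` (1/s), `plateau`, `half_time` (s),
#'   `percent_recovery`, `converged`, `flag` (`"ok"`, `"no_recovery"`,
#'   `"overshoot"` or `"no_convergence"`), `residual_sd`.
#' @export
fit_recovery <- function(normalized) {
  t <- normalized$post_time_s
  y <- normalized$post_normalized
  stopifnot(length(t) >= 5, length(t) == length(y))
  if (max(abs(y)) < 1e-12 || stats::sd(y) == 0) {
    return(structure(list(rate = NA_real_, plateau = 0, half_time = NA_real_,
                          percent_recovery = 0, converged = TRUE,
                          flag = "no_recovery", residual_sd = 0),
                     class = "frap_fit"))
  }
  A0 <- max(stats::median(y[t >= stats::median(t)]), 1e-3)
  thalf_guess <- t[which(y >= A0 / 2)[1]]
  k0 <- if (is.na(thalf_guess) || thalf_guess <= 0) 0.1 else log(2) / thalf_guess
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)),
                      start = list(A = A0, k = k0),
                      lower = c(0, 1e-8), upper = c(5, 100),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(rate = NA_real_, plateau = NA_real_,
                          half_time = NA_real_, percent_recovery = NA_real_,
                          converged = FALSE, flag = "no_convergence",
                          residual_sd = stats::sd(y)),
                     class = "frap_fit"))
  }
  cf <- stats::coef(fit)
  flag <- if (cf[["A"]] > 1) "overshoot" else "ok"
  structure(
    list(rate = cf[["k"]], plateau = cf[["A"]],
         half_time = log(2) / cf[["k"]],
         percent_recovery = 100 * cf[["A"]],
         converged = TRUE, flag = flag,
         residual_sd = stats::sd(stats::resid(fit))),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("FRAP fit: half-time %.3g s, recovery %.1f%% (k = %.4g /s)%s\n",
              x$half_time, x$percent_recovery, x$rate,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}
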