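#' Extract immobile dwells from slow-regime tracks
#'
#' Splits each track into maximal runs of consecutive frames whose
#' inter-frame displacement stays below `r_immobile`; each retained run
#' becomes one dwell of duration `n_frames * frame_interval`, where
#' `n_frames` counts the localizations in the run. Runs shorter than
#' `min_frames` are dropped. A run that ends because the track disappears
#' (track end or a frame gap) is flagged censored — the molecule may have
#' unbound or bleached; a run terminated by a large displacement is an
#' observed unbinding.
#'
#' This displacement-threshold criterion stands in for the kymograph-based
#' immobile-segment calling used on real movies, which is not an explicit
#' algorithm; the threshold is configurable.
#'
#' @param trackset A [track_set()] with regime `"slow"`.
#' @param r_immobile Maximum inter-frame displacement of an immobile
#'   molecule, in um (default 0.2).
#' @param min_frames Minimum run length in frames (default 5).
#' @return A [dwell_set()].
#' @export
extract_dwells <- function(trackset, r_immobile = 0.2, min_frames = 5L) {
  stopifnot(inherits(trackset, "track_set"))
  if (trackset$regime != "slow") {
    stop("dwell extraction is defined for the slow regime", call. = FALSE)
  }
  if (r_immobile <= 0) stop("r_immobile must be > 0", call. = FALSE)
  min_frames <- as.integer(min_frames)
  if (min_frames < 1L) stop("min_frames must be >= 1", call. = FALSE)
  durations <- numeric(0)
  censored <- logical(0)
  for (tr in trackset$tracks) {
    p <- tr$points
    n <- nrow(p)
    if (n == 0L) next
    if (n == 1L) {
      immobile_link <- logical(0)
    } else {
      d <- sqrt(diff(p$x)^2 + diff(p$y)^2)
      immobile_link <- (diff(p$frame) == 1L) & (d < r_immobile)
    }
    # run boundaries: position i starts a run if link i-1 is broken
    run_id <- cumsum(c(TRUE, !immobile_link))
    for (rid in unique(run_id)) {
      idx <- which(run_id == rid)
      m <- length(idx)
      if (m < min_frames) next
      last <- idx[m]
      # censored unless the run was terminated by a large same-frame-step jump
      ended_by_jump <- last < n && p$frame[last + 1L] - p$frame[last] == 1L
      durations <- c(durations, m * trackset$dt)
      censored <- c(censored, !ended_by_jump)
    }
  }
  dwell_set(durations, censored, frame_interval = trackset$dt,
            min_duration = min_frames * trackset$dt)
}

#' Empirical survival (1-CDF) of dwell durations
#'
#' Builds the complement cumulative distribution of observed dwell
#' durations, `S(t) = P(duration >= t)`, normalized to 1 at the minimum
#' duration. Censored events are included as observed durations by default,
#' mirroring a raw 1-CDF of track durations; set `censoring = "exclude"` to
#' drop them, or `"km"` for a Kaplan-Meier estimate (requires the
#' `survival` package).
#'
#' @param dwells A [dwell_set()] with at least one dwell.
#' @param censoring `"include"` (default), `"exclude"` or `"km"`.
#' @return An object of class `survival_curve`: `times` (ascending,
#'   starting at the minimum duration), `survival`, `corrected` flag,
#'   `k_b_applied` (NA until corrected), `n_molecules`.
#' @export
survival_curve <- function(dwells, censoring = c("include", "exclude", "km")) {
  stopifnot(inherits(dwells, "dwell_set"))
  censoring <- match.arg(censoring)
  dur <- dwells$durations
  cen <- dwells$censored
  if (censoring == "exclude") {
    dur <- dur[!cen]
    cen <- cen[!cen]
  }
  if (length(dur) == 0L) stop("no dwells to build a survival curve from",
                              call. = FALSE)
  t0 <- dwells$min_duration
  if (censoring == "km") {
    if (!requireNamespace("survival", quietly = TRUE)) {
      stop("censoring = 'km' requires the survival package", call. = FALSE)
    }
    sf <- survival::survfit(survival::Surv(dur, !cen) ~ 1)
    times <- unique(c(t0, sf$time))
    # survfit gives P(T > t); shift to P(T >= t) on the event grid
    s_right <- stats::approx(sf$time, sf$surv, xout = times,
                             method = "constant", f = 0,
                             yleft = 1, rule = 2)$y
    s <- c(1, s_right[-length(s_right)])
    s <- s / s[1]
  } else {
    times <- sort(unique(c(t0, dur)))
    s <- vapply(times, function(t) mean(dur >= t - 1e-9), numeric(1))
    s <- s / s[1]
  }
  structure(
    list(times = times, survival = s, corrected = FALSE,
         k_b_applied = NA_real_, n_molecules = length(dur),
         min_duration = t0, censoring = censoring),
    class = "survival_curve"
  )
}

#' Evaluate a survival curve at arbitrary times
#'
#' Step interpolation of `S(t) = P(duration >= t)`: on `(t_k, t_k+1]` the
#' curve takes the value stored at `t_k+1`; before the first time it is 1,
#' beyond the last observed duration it is 0.
#'
#' @param curve A [survival_curve()].
#' @param t Vector of times (s).
#' @return Vector of survival values.
#' @export
survival_eval <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  vapply(t, function(ti) {
    if (ti <= curve$times[1]) return(curve$survival[1])
    if (ti > curve$times[length(curve$times)] + 1e-9) return(0)
    idx <- which(curve$times >= ti - 1e-9)[1]
    curve$survival[idx]
  }, numeric(1))
}

#' Estimate the photobleaching rate from an H2B dwell distribution
#'
#' Fits a multi-exponential decay `sum_j w_j * exp(-lambda_j * (t - t0))`
#' to the empirical survival of H2B dwells by bounded nonlinear least
#' squares (weights and rates constrained non-negative) and returns the
#' slowest fitted rate as the photobleaching rate `k_b`: stably
#' incorporated H2B does not unbind on the experiment's timescale, so the
#' slowest decay of its apparent residence-time distribution is bleaching.
#'
#' @param h2b_dwells A [dwell_set()] from the H2B control (>= 500 dwells
#'   recommended; fewer triggers a warning).
#' @param n_components Number of exponential components (default 2).
#' @return An object of class `bleach_estimate`: `k_b` (slowest rate),
#'   `rates`, `weights`, `n_components`.
#' @export
estimate_bleach_rate <- function(h2b_dwells, n_components = 2L) {
  stopifnot(inherits(h2b_dwells, "dwell_set"))
  n_components <- as.integer(n_components)
  if (length(h2b_dwells$durations) < 500L) {
    warning("fewer than 500 H2B dwells; bleach-rate estimate may be noisy")
  }
  curve <- survival_curve(h2b_dwells)
  t0 <- curve$min_duration
  # fit on the regular frame grid so every plateau contributes once
  tg <- seq(t0, max(curve$times), by = h2b_dwells$frame_interval)
  sg <- survival_eval(curve, tg)
  # crude rate scale from the overall decay to seed the multi-start
  tail_idx <- which(sg < 0.5)[1]
  k_scale <- if (is.na(tail_idx)) 1 / (max(tg) - t0 + 1e-9) else
    log(2) / (tg[tail_idx] - t0 + 1e-9)
  fits <- list()
  for (spread in c(4, 10, 25)) {
    lam0 <- k_scale * spread^(seq_len(n_components) / n_components - 0.5)
    w0 <- rep(1 / n_components, n_components)
    start <- c(w0, lam0)
    names(start) <- c(paste0("w", seq_len(n_components)),
                      paste0("l", seq_len(n_components)))
    model <- function(par, t) {
      w <- par[seq_len(n_components)]
      l <- par[n_components + seq_len(n_components)]
      colSums(w * exp(-outer(l, t - t0)))
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start,
        fn = function(par) model(par, tg) - sg,
        lower = rep(c(0, 1e-6), each = n_components),
        upper = rep(c(2, 100), each = n_components),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  if (length(fits) == 0L) stop("bleach-rate fit failed", call. = FALSE)
  dev <- vapply(fits, stats::deviance, numeric(1))
  best <- fits[[which.min(dev)]]
  w <- best$par[seq_len(n_components)]
  l <- best$par[n_components + seq_len(n_components)]
  o <- order(l)
  w <- w[o]; l <- l[o]
  # a vanishing-weight component is a fitting artifact, not a decay rate
  real <- w > 1e-3 * sum(w)
  w <- w[real]; l <- l[real]
  if (length(l) > 1L && any(l[-1] / l[-length(l)] < 3)) {
    warning("exponential components separated by < 3x; ",
            "rates may be poorly identifiable")
  }
  structure(
    list(k_b = unname(l[1]), rates = unname(l), weights = unname(w),
         n_components = n_components, sse = min(dev)),
    class = "bleach_estimate"
  )
}

#' Correct a survival curve for photobleaching
#'
#' Divides the observed survival by `exp(-k_b * t)` (absolute time) and
#' renormalizes so the corrected curve is 1 at the minimum duration; the
#' normalization absorbs the constant that distinguishes the absolute-time
#' form from the offset form `exp(-k_b * (t - t0))`.
#'
#' @param curve An uncorrected [survival_curve()].
#' @param k_b Photobleaching rate in 1/s (>= 0).
#' @return A corrected `survival_curve` with `k_b_applied` recorded.
#' @export
correct_bleaching <- function(curve, k_b) {
  stopifnot(inherits(curve, "survival_curve"))
  if (curve$corrected) {
    stop("curve is already bleach-corrected; refusing to correct twice",
         call. = FALSE)
  }
  if (!is.finite(k_b) || k_b < 0) stop("k_b must be >= 0", call. = FALSE)
  s <- curve$survival / exp(-k_b * curve$times)
  s <- s / s[1]
  if (max(s) > 10) {
    warning("corrected survival exceeds 10x; k_b may over-correct this curve")
  }
  out <- curve
  out$survival <- s
  out$corrected <- TRUE
  out$k_b_applied <- k_b
  out
}

# trapezoidal integral of the step-interpolated curve over [t_lo, t_hi]
.rmst_trapz <- function(curve, t_lo, t_hi) {
  grid <- sort(unique(c(t_lo, curve$times[curve$times > t_lo &
                                            curve$times < t_hi], t_hi)))
  s <- survival_eval(curve, grid)
  sum(diff(grid) * (utils::head(s, -1) + utils::tail(s, -1)) / 2)
}

#' Restricted mean survival and long-binder fraction with resampling errors
#'
#' Summarizes a (typically bleach-corrected) residence-time survival curve
#' by the restricted mean survival time — the trapezoidal integral of
#' `S(t)` over the observation window, 2.5 s to 100 s by default — and the
#' fraction of binding events outliving the window (`S(100)`). Error bars
#' are the standard deviations of each statistic over delete-half
#' resampling: `n_resamples` replicates each drop a random half of the
#' dwells, rebuild the curve (re-applying the same bleaching correction)
#' and recompute both statistics.
#'
#' @param curve A [survival_curve()] built from `dwells`. If uncorrected,
#'   set `allow_uncorrected = TRUE` to proceed.
#' @param dwells The [dwell_set()] underlying `curve`.
#' @param window Length-2 analysis window in seconds (default `c(2.5, 100)`).
#' @param n_resamples Number of delete-half replicates (default 1000).
#' @param drop_fraction Fraction of dwells dropped per replicate
#'   (default 0.5).
#' @param seed Integer seed for the resampling.
#' @param allow_uncorrected Permit summarizing an uncorrected curve.
#' @return An object of class `residence_summary`: `rmst`, `frac_gt_end`,
#'   `err_rmst`, `err_frac`, `window`, `n_molecules`.
#' @export
summarize_residence <- function(curve, dwells, window = c(2.5, 100),
                                n_resamples = 1000L, drop_fraction = 0.5,
                                seed = 1L, allow_uncorrected = FALSE) {
  stopifnot(inherits(curve, "survival_curve"), inherits(dwells, "dwell_set"))
  if (!curve$corrected && !allow_uncorrected) {
    stop("curve is not bleach-corrected; pass allow_uncorrected = TRUE ",
         "to summarize it anyway", call. = FALSE)
  }
  if (window[2] <= window[1]) stop("invalid window", call. = FALSE)
  if (!is.null(dwells$movie_length) && window[2] > dwells$movie_length) {
    stop("window end ", window[2], " s exceeds the movie length (",
         dwells$movie_length, " s); truncate the window", call. = FALSE)
  }
  rmst <- .rmst_trapz(curve, window[1], window[2])
  frac <- survival_eval(curve, window[2])

  n <- length(dwells$durations)
  n_drop <- floor(drop_fraction * n)
  stats_rep <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_resamples), function(i) {
      keep <- sample.int(n, n - n_drop)
      sub <- dwell_set(dwells$durations[keep], dwells$censored[keep],
                       frame_interval = dwells$frame_interval,
                       min_duration = dwells$min_duration,
                       movie_length = dwells$movie_length)
      sc <- survival_curve(sub, censoring = curve$censoring)
      if (curve$corrected) sc <- correct_bleaching(sc, curve$k_b_applied)
      c(.rmst_trapz(sc, window[1], window[2]),
        survival_eval(sc, window[2]))
    }, numeric(2))
  })
  structure(
    list(rmst = rmst, frac_gt_end = frac,
         err_rmst = stats::sd(stats_rep[1, ]),
         err_frac = stats::sd(stats_rep[2, ]),
         window = window, n_molecules = curve$n_molecules,
         n_resamples = n_resamples, drop_fraction = drop_fraction),
    class = "residence_summary"
  )
}

#' @export
print.residence_summary <- function(x, ...) {
  cat(sprintf(
    "residence_summary (n = %d): RMST[%g, %g s] = %.2f +/- %.2f s; S(%g s) = %.3f +/- %.3f\n",
    x$n_molecules, x$window[1], x$window[2], x$rmst, x$err_rmst,
    x$window[2], x$frac_gt_end, x$err_frac))
  invisible(x)
}
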