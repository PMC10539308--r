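#' Histogram of jump magnitudes
#'
#' Bins displacement magnitudes into `[k*bin_width, (k+1)*bin_width)` bins
#' up to `r_max`; jumps at or beyond `r_max` are tallied in a separate
#' overflow counter so that `sum(counts) + overflow == n_jumps`.
#'
#' @param jumps Numeric vector of jump magnitudes (um).
#' @param bin_width Bin size in um (default 0.020 um, i.e. 20 nm).
#' @param r_max Histogram range in um (default 1.5).
#' @param dt Frame interval in seconds (default 0.01).
#' @param cell_id Optional cell label carried through to the fit.
#' @return An object of class `jump_histogram` with fields `breaks`,
#'   `mids`, `counts`, `overflow`, `n_jumps`, `bin_width`, `dt`, `cell_id`.
#' @export
jump_histogram <- function(jumps, bin_width = 0.020, r_max = 1.5,
                           dt = 0.01, cell_id = NA_character_) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  if (length(jumps) == 0L) {
    stop("no jumps to histogram", if (!is.na(cell_id)) paste0(" (cell ", cell_id, ")"),
         call. = FALSE)
  }
  nb <- ceiling(r_max / bin_width)
  breaks <- seq(0, nb * bin_width, by = bin_width)
  inside <- jumps < breaks[length(breaks)]
  counts <- tabulate(findInterval(jumps[inside], breaks,
                                  rightmost.closed = FALSE), nbins = nb)
  structure(
    list(breaks = breaks, mids = breaks[-length(breaks)] + bin_width / 2,
         counts = counts, overflow = sum(!inside),
         n_jumps = length(jumps), bin_width = bin_width, dt = dt,
         cell_id = cell_id),
    class = "jump_histogram"
  )
}

#' Per-cell displacement histograms from a fast-regime track set
#'
#' @param trackset A [track_set()] with regime `"fast"`.
#' @param bin_width,r_max See [jump_histogram()].
#' @param pooled If `TRUE`, also include a histogram of all cells pooled
#'   under the name `"pooled"`.
#' @return Named list of `jump_histogram`s, one per cell.
#' @export
build_jump_histogram <- function(trackset, bin_width = 0.020, r_max = 1.5,
                                 pooled = FALSE) {
  stopifnot(inherits(trackset, "track_set"))
  if (trackset$regime != "fast") {
    stop("displacement histograms are defined for the fast regime",
         call. = FALSE)
  }
  jl <- extract_jumps(trackset, by_cell = TRUE)
  out <- lapply(names(jl), function(cell) {
    jump_histogram(jl[[cell]], bin_width = bin_width, r_max = r_max,
                   dt = trackset$dt, cell_id = cell)
  })
  names(out) <- names(jl)
  if (pooled) {
    out$pooled <- jump_histogram(unlist(jl, use.names = FALSE),
                                 bin_width = bin_width, r_max = r_max,
                                 dt = trackset$dt, cell_id = "pooled")
  }
  out
}

#' Model probability of a displacement per histogram bin
#'
#' Evaluates the three-state displacement model at the bin centers:
#' `p(r) = r * dr * sum_i F_i / (2 * D_i * dt) * exp(-r^2 / (4 * D_i * dt))`,
#' the probability of observing a jump in the bin of width `dr` centered at
#' `r`. A state with `D_i = 0` is a point mass: its whole fraction is
#' assigned to the first bin.
#'
#' @param params A [diffusion_params()] object.
#' @param bin_centers Positive bin-center magnitudes (um).
#' @param bin_width Bin width in um.
#' @return Vector of per-bin probabilities.
#' @export
displacement_bin_prob <- function(params, bin_centers, bin_width) {
  stopifnot(inherits(params, "diffusion_params"))
  if (any(bin_centers <= 0)) {
    stop("bin centers must be positive", call. = FALSE)
  }
  p <- numeric(length(bin_centers))
  for (i in 1:3) {
    D <- params$coeffs[i]
    if (D > 0) {
      v <- 4 * D * params$dt
      p <- p + params$fractions[i] * bin_centers * bin_width / (v / 2) *
        exp(-bin_centers^2 / v)
    } else {
      p[1] <- p[1] + params$fractions[i]
    }
  }
  p
}

# Stick-breaking map between the unconstrained optimizer scale and
# (F1, F2, F3) on the simplex with log-scaled coefficients.
.theta_to_params <- function(theta, dt) {
  s1 <- theta[1]; s2 <- theta[2]
  f1 <- s1
  f2 <- (1 - s1) * s2
  d <- exp(theta[3:5])
  o <- order(d)
  f <- c(f1, f2, 1 - f1 - f2)[o]
  # renormalize away accumulated floating error so the simplex invariant holds
  f <- pmax(f, 0); f <- f / sum(f)
  diffusion_params(f, sort(unique_eps(d)), dt = dt)
}

# nudge exactly-tied coefficients apart so the D1 < D2 < D3 invariant holds
unique_eps <- function(d) {
  d <- sort(d)
  for (i in 2:length(d)) if (d[i] <= d[i - 1]) d[i] <- d[i - 1] * (1 + 1e-9)
  d
}

#' Fit the three-component displacement model to a jump histogram
#'
#' Nonlinear least squares of the model bin probabilities
#' ([displacement_bin_prob()]) against the empirical bin fractions of one
#' cell's histogram. Fractions are parameterized on the simplex
#' (stick-breaking) and coefficients on the log scale within box bounds;
#' the optimizer is run from a multi-start grid of log-spaced coefficient
#' triples and the best residual sum of squares wins (ties broken by lower
#' D1). Components in the returned estimate are sorted so D1 < D2 < D3.
#'
#' @param hist A [jump_histogram()].
#' @param init Optional [diffusion_params()] used as an additional start.
#' @param d_bounds 2x3 matrix of lower/upper bounds for (D1, D2, D3) in
#'   um^2/s; default `rbind(c(1e-3, 0.05, 0.5), c(0.1, 2, 20))`.
#' @param fix_d1 Optional value at which to pin the slowest coefficient
#'   (e.g. 0.034); default `NULL`, D1 free.
#' @param n_starts Number of multi-start points (default 8).
#' @param min_jumps Minimum recommended number of jumps (default 1000);
#'   below this a warning is issued but the fit is still attempted.
#' @return An object of class `diffusion_fit`: fields `params`
#'   ([diffusion_params()]), `sse`, `converged`, `n_jumps`, `cell_id`.
#' @export
fit_three_component <- function(hist, init = NULL,
                                d_bounds = rbind(c(1e-3, 0.05, 0.5),
                                                 c(0.1, 2, 20)),
                                fix_d1 = NULL, n_starts = 8L,
                                min_jumps = 1000L) {
  stopifnot(inherits(hist, "jump_histogram"))
  if (hist$n_jumps < min_jumps) {
    warning("only ", hist$n_jumps, " jumps (< ", min_jumps,
            "); fit may be unstable")
  }
  emp <- hist$counts / hist$n_jumps
  mids <- hist$mids
  bw <- hist$bin_width
  dt <- hist$dt

  obj <- function(theta) {
    if (!is.null(fix_d1)) theta[3] <- log(fix_d1)
    p <- .theta_to_params(theta, dt)
    sum((displacement_bin_prob(p, mids, bw) - emp)^2)
  }

  lo <- c(1e-6, 1e-6, log(d_bounds[1, ]))
  hi <- c(1 - 1e-6, 1 - 1e-6, log(d_bounds[2, ]))

  # log-spaced grid of starts spanning the bound boxes
  grid <- lapply(seq_len(n_starts), function(k) {
    fr <- (k - 0.5) / n_starts
    c(0.4, 0.5,
      log(d_bounds[1, ]) + fr * (log(d_bounds[2, ]) - log(d_bounds[1, ])))
  })
  if (!is.null(init)) {
    stopifnot(inherits(init, "diffusion_params"))
    f <- init$fractions
    grid <- c(grid, list(c(f[1], if (f[1] < 1) f[2] / (1 - f[1]) else 0.5,
                           log(pmin(pmax(init$coeffs, d_bounds[1, ]),
                                    d_bounds[2, ])))))
  }

  best <- NULL
  for (start in grid) {
    res <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-15 ||
        (abs(res$value - best$value) <= 1e-15 &&
         res$par[3] < best$par[3])) {
      best <- res
    }
  }
  if (is.null(best)) {
    stop("three-component fit failed to converge from any start",
         call. = FALSE)
  }
  theta <- best$par
  if (!is.null(fix_d1)) theta[3] <- log(fix_d1)
  structure(
    list(params = .theta_to_params(theta, dt), sse = best$value,
         converged = best$convergence == 0L, n_jumps = hist$n_jumps,
         cell_id = hist$cell_id),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("diffusion_fit (cell %s, %d jumps, sse = %.3g, converged = %s)\n",
              x$cell_id, x$n_jumps, x$sse, x$converged))
  print(x$params)
  invisible(x)
}

#' Tabulate per-cell three-component fits
#'
#' @param fits List of `diffusion_fit` objects.
#' @return Data frame with one row per cell: fractions, coefficients, sse,
#'   convergence flag and jump count.
#' @export
fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(cell_id = f$cell_id,
               F1 = f$params$fractions[1], F2 = f$params$fractions[2],
               F3 = f$params$fractions[3],
               D1 = f$params$coeffs[1], D2 = f$params$coeffs[2],
               D3 = f$params$coeffs[3],
               sse = f$sse, converged = f$converged, n_jumps = f$n_jumps,
               row.names = NULL)
  }))
}

#' Compare per-cell diffusion statistics across conditions
#'
#' Rank-based Kruskal-Wallis test of each per-cell statistic (bound
#' fraction, slow fraction, the three coefficients, ...) across two or more
#' conditions, with per-condition medians and quartiles. Ties are handled
#' by the test's tie correction.
#'
#' @param stats_df Data frame with a `condition` column plus one numeric
#'   column per statistic (e.g. the output of [fit_table()] with a
#'   condition column added).
#' @param statistics Character vector of columns to test; default all
#'   numeric columns except `condition`.
#' @return List with `tests` (data frame: statistic, H, df, p_value) and
#'   `summaries` (data frame of per-condition median and quartiles).
#' @export
compare_groups <- function(stats_df, statistics = NULL) {
  if (!"condition" %in% names(stats_df)) {
    stop("stats_df needs a 'condition' column", call. = FALSE)
  }
  cond <- factor(stats_df$condition)
  if (nlevels(cond) < 2L) stop(">= 2 conditions required", call. = FALSE)
  if (any(table(cond) < 2L)) stop("each condition needs >= 2 cells", call. = FALSE)
  if (is.null(statistics)) {
    statistics <- names(stats_df)[vapply(stats_df, is.numeric, logical(1))]
  }
  tests <- do.call(rbind, lapply(statistics, function(s) {
    kt <- stats::kruskal.test(stats_df[[s]], cond)
    data.frame(statistic = s, H = unname(kt$statistic),
               df = unname(kt$parameter), p_value = kt$p.value,
               row.names = NULL)
  }))
  summaries <- do.call(rbind, lapply(statistics, function(s) {
    do.call(rbind, lapply(levels(cond), function(cl) {
      v <- stats_df[[s]][cond == cl]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(statistic = s, condition = cl, n = length(v),
                 q1 = q[1], median = q[2], q3 = q[3], row.names = NULL)
    }))
  }))
  list(tests = tests, summaries = summaries)
}
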