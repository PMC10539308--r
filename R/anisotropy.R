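#' Quadratic (ligand-depletion) binding isotherm
#'
#' Anisotropy of a labelled probe at total concentration `c` titrated with
#' protein at total concentration `x`:
#' `y = b0 + (bmax - b0) * (c + x + kd - sqrt((c + x + kd)^2 - 4*c*x)) / (2*c)`.
#' The quadratic form accounts for probe depletion, which matters when `c`
#' is comparable to `kd`; as `c -> 0` it converges to the hyperbola
#' `b0 + (bmax - b0) * x / (x + kd)`. The discriminant is non-negative for
#' valid inputs and is clamped at 0 against floating-point error.
#'
#' @param x Protein concentrations (nM, >= 0); vectorized.
#' @param kd Dissociation constant (nM, > 0).
#' @param b0 Anisotropy of the free probe (fitted minimum).
#' @param bmax Anisotropy of the fully bound probe (fitted maximum).
#' @param c Probe concentration (nM, > 0; default 1.33 nM as in the assay).
#' @return Anisotropy values, same length as `x`.
#' @export
anisotropy_isotherm <- function(x, kd, b0, bmax, c = 1.33) {
  if (!is.finite(kd) || kd <= 0) stop("kd must be > 0", call. = FALSE)
  if (!is.finite(c) || c <= 0) stop("c must be > 0", call. = FALSE)
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  s <- c + x + kd
  disc <- s^2 - 4 * c * x
  if (any(disc < -1e-6 * s^2)) {
    stop("internal error: negative discriminant in binding isotherm",
         call. = FALSE)
  }
  bound_frac <- (s - sqrt(pmax(disc, 0))) / (2 * c)
  b0 + (bmax - b0) * bound_frac
}

#' Simulate anisotropy titrations
#'
#' Evaluates the quadratic isotherm on a protein-concentration grid and
#' adds i.i.d. Gaussian noise, one series per replicate.
#'
#' @param kd,b0,bmax,c Isotherm parameters; see [anisotropy_isotherm()].
#' @param x_grid Ascending non-negative protein concentrations (nM).
#' @param noise_sd Gaussian noise standard deviation (anisotropy units).
#' @param n_replicates Number of replicate series (default 3).
#' @param seed Integer seed.
#' @param probe_id Probe label attached to the series (default "probe").
#' @return Data frame (`probe_id`, `replicate`, `protein_nM`, `anisotropy`)
#'   with a `ground_truth` attribute.
#' @export
simulate_titration <- function(kd, b0, bmax, c = 1.33, x_grid,
                               noise_sd = 0, n_replicates = 3L, seed,
                               probe_id = "probe") {
  if (bmax == b0) stop("bmax must differ from b0", call. = FALSE)
  if (is.unsorted(x_grid) || any(x_grid < 0)) {
    stop("x_grid must be non-negative and ascending", call. = FALSE)
  }
  y0 <- anisotropy_isotherm(x_grid, kd, b0, bmax, c)
  df <- withr::with_seed(as.integer(seed), {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      data.frame(probe_id = probe_id, replicate = paste0("rep", r),
                 protein_nM = x_grid,
                 anisotropy = y0 + stats::rnorm(length(x_grid), 0, noise_sd))
    }))
  })
  attr(df, "ground_truth") <- list(
    generator = "simulate_titration", kd = kd, b0 = b0, bmax = bmax, c = c,
    x_grid = x_grid, noise_sd = noise_sd, n_replicates = n_replicates,
    seed = as.integer(seed)
  )
  df
}

# fit one replicate series; returns list(kd, b0, bmax, converged)
.fit_kd_one <- function(x, y, c) {
  half <- min(y) + 0.5 * (max(y) - min(y))
  kd0 <- x[which.min(abs(y - half))]
  if (kd0 <= 0) kd0 <- max(stats::median(x[x > 0]), 1e-3)
  start <- c(kd = kd0, b0 = min(y), dB = max(y) - min(y))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      fn = function(p) {
        anisotropy_isotherm(x, p[["kd"]], p[["b0"]], p[["b0"]] + p[["dB"]],
                            c) - y
      },
      lower = c(1e-6, -Inf, 1e-9),
      upper = c(1e9, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(list(kd = NA_real_, b0 = NA_real_, bmax = NA_real_,
                converged = FALSE))
  }
  p <- fit$par
  list(kd = unname(p[["kd"]]), b0 = unname(p[["b0"]]),
       bmax = unname(p[["b0"]] + p[["dB"]]), converged = TRUE)
}

#' Fit the dissociation constant to replicate titrations
#'
#' Per-replicate bounded nonlinear least squares of the quadratic isotherm
#' with `kd`, `b0` and `bmax` free (`bmax > b0` enforced); the reported
#' `kd` is the mean of the replicate estimates with their standard
#' deviation, matching an assay analyzed as independent triplicates. A
#' pooled mode fits all points of all replicates jointly instead.
#'
#' @param series Data frame with columns `replicate`, `protein_nM`,
#'   `anisotropy` (baseline-subtracted); if a `baseline` column is present
#'   it is subtracted first. Each replicate needs >= 4 distinct
#'   concentrations.
#' @param c Probe concentration in nM (default 1.33).
#' @param pooled If `TRUE`, fit all replicates jointly and report that
#'   single estimate (sd `NA`).
#' @return An object of class `kd_fit`: `kd` (mean), `kd_sd`,
#'   `replicate_kds`, `b0`, `bmax`, `converged`.
#' @export
fit_kd <- function(series, c = 1.33, pooled = FALSE) {
  need <- c("replicate", "protein_nM", "anisotropy")
  if (!all(need %in% names(series))) {
    stop("series needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  y <- series$anisotropy
  if ("baseline" %in% names(series)) y <- y - series$baseline
  if (pooled) {
    f <- .fit_kd_one(series$protein_nM, y, c)
    return(structure(
      list(kd = f$kd, kd_sd = NA_real_, replicate_kds = f$kd,
           b0 = f$b0, bmax = f$bmax, converged = f$converged),
      class = "kd_fit"
    ))
  }
  reps <- split(seq_len(nrow(series)), series$replicate)
  fits <- lapply(reps, function(idx) {
    if (length(unique(series$protein_nM[idx])) < 4L) {
      stop("each replicate needs >= 4 distinct concentrations",
           call. = FALSE)
    }
    .fit_kd_one(series$protein_nM[idx], y[idx], c)
  })
  ok <- vapply(fits, `[[`, logical(1), "converged")
  if (!all(ok)) {
    warning(sum(!ok), " replicate fit(s) failed to converge; ",
            "excluded from the mean")
  }
  kds <- vapply(fits, `[[`, numeric(1), "kd")[ok]
  structure(
    list(kd = mean(kds), kd_sd = stats::sd(kds),
         replicate_kds = stats::setNames(
           vapply(fits, `[[`, numeric(1), "kd"), names(fits)),
         b0 = mean(vapply(fits, `[[`, numeric(1), "b0")[ok]),
         bmax = mean(vapply(fits, `[[`, numeric(1), "bmax")[ok]),
         converged = any(ok)),
    class = "kd_fit"
  )
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("kd_fit: KD = %.3g +/- %.3g nM (%d replicate(s)), b0 = %.4g, bmax = %.4g\n",
              x$kd, x$kd_sd, length(x$replicate_kds), x$b0, x$bmax))
  invisible(x)
}

#' Compare dissociation constants across conditions
#'
#' Pairwise affinity ratios and unpaired two-tailed t-tests on the
#' replicate-level KD estimates of each condition. Conditions with fewer
#' than two replicates get their ratio reported with the test skipped (a
#' warning is raised).
#'
#' @param fits Named list of [fit_kd()] results, one per condition
#'   (protein/probe combination).
#' @param reference Optional condition name; if given, only ratios relative
#'   to it are reported, otherwise all pairs.
#' @return Data frame: `condition_a`, `condition_b`, `kd_a`, `kd_b`,
#'   `ratio` (kd_a / kd_b), `p_value`.
#' @export
compare_kd <- function(fits, reference = NULL) {
  stopifnot(length(fits) >= 2L, !is.null(names(fits)))
  pairs <- if (is.null(reference)) {
    utils::combn(names(fits), 2, simplify = FALSE)
  } else {
    lapply(setdiff(names(fits), reference), function(a) c(a, reference))
  }
  do.call(rbind, lapply(pairs, function(pr) {
    fa <- fits[[pr[1]]]; fb <- fits[[pr[2]]]
    ka <- fa$replicate_kds[is.finite(fa$replicate_kds)]
    kb <- fb$replicate_kds[is.finite(fb$replicate_kds)]
    p <- if (length(ka) >= 2L && length(kb) >= 2L) {
      stats::t.test(ka, kb, var.equal = FALSE)$p.value
    } else {
      warning("condition with < 2 replicates: t-test skipped for ",
              pr[1], " vs ", pr[2])
      NA_real_
    }
    data.frame(condition_a = pr[1], condition_b = pr[2],
               kd_a = fa$kd, kd_b = fb$kd, ratio = fa$kd / fb$kd,
               p_value = p, row.names = NULL)
  }))
}

#' Per-concentration t-tests between two titration series
#'
#' The point-level comparison mode: at each shared protein concentration,
#' an unpaired two-tailed t-test of the replicate anisotropy values of the
#' two conditions.
#'
#' @param series_a,series_b Titration data frames as in [fit_kd()].
#' @return Data frame: `protein_nM`, `mean_a`, `mean_b`, `p_value`.
#' @export
compare_titration_points <- function(series_a, series_b) {
  xs <- intersect(unique(series_a$protein_nM), unique(series_b$protein_nM))
  do.call(rbind, lapply(sort(xs), function(x) {
    ya <- series_a$anisotropy[series_a$protein_nM == x]
    yb <- series_b$anisotropy[series_b$protein_nM == x]
    p <- if (length(ya) >= 2L && length(yb) >= 2L) {
      stats::t.test(ya, yb, var.equal = FALSE)$p.value
    } else NA_real_
    data.frame(protein_nM = x, mean_a = mean(ya), mean_b = mean(yb),
               p_value = p)
  }))
}
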