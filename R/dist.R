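#' Distribution specifications for Monte Carlo inputs
#'
#' Every random input to the exposure model (a concentration, a body weight,
#' an intake volume) is described by a `dist_spec`: a distribution family with
#' its parameters, an optional clamp-at-zero flag, and for triangular specs an
#' interpretation flag saying whether the three numbers are (min, mode, max)
#' or the 10th/50th/90th percentiles of the distribution.
#'
#' Clamping follows the convention of probabilistic dietary assessments that
#' report zero-inflated intake distributions: a negative draw from a wide
#' normal is kept and set to 0.0 (a non-consumption day), not rejected.
#'
#' @param low,high uniform bounds, `low <= high`.
#' @param mean,sd normal parameters, `sd >= 0`.
#' @param a,b,c triangular parameters; under `"min_mode_max"` these are
#'   minimum, mode, maximum with `a <= b <= c`; under `"p10_p50_p90"` they are
#'   strictly increasing percentiles and the (min, mode, max) triple is
#'   recovered numerically by [fit_triangular_from_percentiles()], clamping
#'   any negative left tail at zero.
#' @param value the constant for a degenerate point mass.
#' @param truncate_at_zero logical; clamp negative draws to 0.
#' @param interpretation triangular interpretation flag.
#' @return an object of class `dist_spec`.
#' @examples
#' dist_uniform(0, 0.010)                     # arsenic in water, mg/L
#' dist_normal(14.3, 16.1, truncate_at_zero = TRUE)  # rice cereal, g/day
#' dist_triangular(2.30e-5, 9.10e-5, 2.83e-4)        # arsenic in rice, mg/g
#' @name dist_spec
NULL

new_dist_spec <- function(family, params, truncate_at_zero = FALSE,
                          interpretation = "min_mode_max") {
  spec <- structure(
    list(family = family, params = params,
         truncate_at_zero = isTRUE(truncate_at_zero),
         interpretation = interpretation),
    class = "dist_spec")
  validate_dist_spec(spec)
  spec
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(low, high, truncate_at_zero = FALSE)
  new_dist_spec("uniform", list(low = low, high = high), truncate_at_zero)

#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd, truncate_at_zero = FALSE)
  new_dist_spec("normal", list(mean = mean, sd = sd), truncate_at_zero)

#' @rdname dist_spec
#' @export
dist_triangular <- function(a, b, c,
                            interpretation = c("min_mode_max", "p10_p50_p90"),
                            truncate_at_zero = FALSE) {
  interpretation <- match.arg(interpretation)
  new_dist_spec("triangular", list(a = a, b = b, c = c), truncate_at_zero,
                interpretation)
}

#' @rdname dist_spec
#' @export
dist_point <- function(value)
  new_dist_spec("point", list(value = value))

#' Validate a distribution specification
#'
#' Checks the family-specific invariants: uniform `low <= high`, normal
#' `sd >= 0`, triangular ordering (weak under min/mode/max, strict under the
#' percentile interpretation), point mass with exactly one parameter.
#'
#' @param spec a `dist_spec`.
#' @return `spec`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_dist_spec <- function(spec) {
  if (!inherits(spec, "dist_spec"))
    stop("not a 'dist_spec' object")
  p <- spec$params
  bad <- function(msg) stop(sprintf("invalid %s spec: %s", spec$family, msg),
                            call. = FALSE)
  if (!all(vapply(p, function(z) is.numeric(z) && length(z) == 1L && is.finite(z),
                  logical(1))))
    bad("all parameters must be finite numeric scalars")
  switch(spec$family,
    uniform = if (p$low > p$high) bad("low > high"),
    normal = if (p$sd < 0) bad("sd < 0"),
    triangular = {
      if (spec$interpretation == "min_mode_max") {
        if (!(p$a <= p$b && p$b <= p$c)) bad("requires a <= b <= c")
      } else {
        if (!(p$a < p$b && p$b < p$c))
          bad("percentile interpretation requires strictly increasing values")
      }
    },
    point = if (length(p) != 1L) bad("point mass takes exactly one parameter"),
    bad("unknown family"))
  invisible(spec)
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(%s)%s%s\n", x$family,
              paste(sprintf("%s = %g", names(x$params), unlist(x$params)),
                    collapse = ", "),
              if (x$truncate_at_zero) " [clamped at 0]" else "",
              if (x$family == "triangular" && x$interpretation != "min_mode_max")
                " [p10/p50/p90]" else ""))
  invisible(x)
}

#' Central value of a distribution specification
#'
#' The point used when a scenario is collapsed to its degenerate (point-mass)
#' form: uniform midpoint, normal mean, triangular mode (or p50 under the
#' percentile interpretation), the constant for a point mass.
#'
#' @param spec a `dist_spec`.
#' @return a numeric scalar.
#' @export
dist_central <- function(spec) {
  validate_dist_spec(spec)
  p <- spec$params
  switch(spec$family,
    uniform = (p$low + p$high) / 2,
    normal = p$mean,
    triangular = if (spec$interpretation == "min_mode_max") p$b else p$b,
    point = p$value)
}

#' Triangular quantile function
#'
#' Closed-form inverse CDF of the triangular distribution with minimum `a`,
#' mode `b`, maximum `c`.
#'
#' @param p probabilities in \[0, 1\] (vectorised).
#' @param a,b,c triangular minimum, mode, maximum with `a <= b <= c`.
#' @return quantiles, same length as `p`.
#' @examples
#' triangular_quantile(0.5, 0, 1, 2)   # symmetric: median = mode = 1
#' triangular_quantile(0.1, 0, 1, 2)   # sqrt(0.2)
#' @export
triangular_quantile <- function(p, a, b, c) {
  stopifnot(a <= b, b <= c, all(p >= 0 & p <= 1))
  if (a == c) return(rep(a, length(p)))
  fb <- (b - a) / (c - a)           # CDF at the mode
  q <- ifelse(p <= fb,
              a + sqrt(p * (c - a) * (b - a)),
              c - sqrt((1 - p) * (c - a) * (c - b)))
  q
}

#' Fit a triangular distribution to three percentiles
#'
#' Numerically recovers the (min, mode, max) triple whose 10th, 50th and 90th
#' percentiles match the given values. The problem reduces to a 1-D root find:
#' writing s for the CDF at the mode, every quantile is
#' `a + (c - a) * g_p(s)` with `g_p(s) = sqrt(p s)` for `p <= s` and
#' `1 - sqrt((1 - p)(1 - s))` otherwise, so the ratio
#' `(p50 - p10) / (p90 - p10)` pins down s independently of location and
#' scale.
#'
#' Two infeasibilities are detected and reported rather than hidden. A
#' continuous triangular always has its 10th percentile strictly above its
#' minimum, so a triple with `p10 = 0` forces `a < 0`; `feasible_nonneg`
#' flags whether the fitted minimum is nonnegative, so callers can fall back
#' to sampling with a clamped negative tail. More fundamentally, the ratio
#' `(p50 - p10)/(p90 - p10)` of any triangular lies in a narrow band (about
#' 0.38-0.62); a triple outside it — such as a heavily right-skewed intake
#' triplet — matches no triangular at all. In that case `feasible` is
#' `FALSE` and the returned parameters are the best-effort fit that anchors
#' p10 and p90 exactly and brings p50 as close as possible (the mode
#' degenerates toward the nearer endpoint), with the p50 miss in
#' `residual`.
#'
#' @param p10,p50,p90 strictly increasing target percentiles.
#' @param tol root-finding tolerance (on s).
#' @return a list with elements `a`, `b`, `c`, `feasible` (a triangular with
#'   these exact percentiles exists), `feasible_nonneg` (`feasible` and
#'   `a >= 0`), and `residual` (max absolute quantile error of the fit).
#' @examples
#' fit_triangular_from_percentiles(sqrt(0.2), 1, 2 - sqrt(0.2))  # Tri(0, 1, 2)
#' @export
fit_triangular_from_percentiles <- function(p10, p50, p90, tol = 1e-12) {
  if (!(p10 < p50 && p50 < p90))
    stop("percentiles must be strictly increasing")
  g <- function(p, s) if (p <= s) sqrt(p * s) else 1 - sqrt((1 - p) * (1 - s))
  ratio <- function(s)
    (g(0.5, s) - g(0.1, s)) / (g(0.9, s) - g(0.1, s))
  target <- (p50 - p10) / (p90 - p10)
  lo <- 1e-9; hi <- 1 - 1e-9
  f <- function(s) ratio(s) - target
  feasible <- f(lo) * f(hi) <= 0
  s <- if (feasible) {
    uniroot(f, c(lo, hi), tol = tol)$root
  } else {
    # no exact solution: pick the mode position minimizing the p50 miss
    if (abs(f(lo)) < abs(f(hi))) lo else hi
  }
  scale <- (p90 - p10) / (g(0.9, s) - g(0.1, s))
  a <- p10 - scale * g(0.1, s)
  c_ <- a + scale
  b <- a + s * scale
  resid <- max(abs(triangular_quantile(c(0.1, 0.5, 0.9), a, b, c_) -
                     c(p10, p50, p90)))
  list(a = a, b = b, c = c_, feasible = feasible,
       feasible_nonneg = feasible && a >= -1e-12 * max(1, abs(c_)),
       residual = resid)
}

#' Draw from a distribution specification
#'
#' Samples `n` values from the family described by `spec`. Draws are made
#' under the labelled substream of `stream` so that simulations are exactly
#' reproducible and component-independent. Negative draws are clamped to 0.0
#' when the spec's `truncate_at_zero` flag is set; triangular specs under the
#' percentile interpretation are first converted to (min, mode, max) via
#' [fit_triangular_from_percentiles()] and, if the fitted minimum is
#' negative, the left tail is clamped at zero.
#'
#' @param spec a `dist_spec`.
#' @param n number of draws, `n >= 1`.
#' @param stream an [rng_stream()], or `NULL` to use the current RNG state.
#' @param label substream label (required when `stream` is given).
#' @return numeric vector of length `n`.
#' @export
dist_sample <- function(spec, n, stream = NULL, label = NULL) {
  validate_dist_spec(spec)
  stopifnot(n >= 1)
  draw <- function() {
    p <- spec$params
    x <- switch(spec$family,
      uniform = runif(n, p$low, p$high),
      normal = rnorm(n, p$mean, p$sd),
      triangular = {
        if (spec$interpretation == "min_mode_max") {
          triangular_quantile(runif(n), p$a, p$b, p$c)
        } else {
          fit <- fit_triangular_from_percentiles(p$a, p$b, p$c)
          pmax(triangular_quantile(runif(n), fit$a, fit$b, fit$c), 0)
        }
      },
      point = rep(p$value, n))
    if (spec$truncate_at_zero) pmax(x, 0) else x
  }
  if (is.null(stream)) draw() else with_substream(stream, label, draw())
}

#' Draw daily serving counts
#'
#' Feeding frequencies are given as integer ranges (e.g. 3-4 servings/day).
#' The default draws i.i.d. discrete-uniform integers on
#' `{n_min, ..., n_max}` (a feeding either happens or it does not); a
#' continuous-uniform option is available since published intake tables do
#' not state the sampling rule.
#'
#' @param range integer vector `c(n_min, n_max)` with `0 <= n_min <= n_max`.
#' @param n number of draws.
#' @param stream,label optional [rng_stream()] and substream label.
#' @param mode `"discrete"` (integers) or `"continuous"` (uniform reals).
#' @return numeric vector of length `n`.
#' @export
sample_serving_count <- function(range, n, stream = NULL, label = NULL,
                                 mode = c("discrete", "continuous")) {
  mode <- match.arg(mode)
  stopifnot(length(range) == 2L, range[1] >= 0, range[1] <= range[2])
  draw <- function() {
    if (mode == "discrete") {
      range[1] + floor(runif(n) * (range[2] - range[1] + 1))
    } else {
      runif(n, range[1], range[2])
    }
  }
  if (is.null(stream)) draw() else with_substream(stream, label, draw())
}
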