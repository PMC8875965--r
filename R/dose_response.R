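#' Relative root elongation per treatment
#'
#' \eqn{RRE = 100 (\bar L_{f,t} - \bar L_{i,t}) / (\bar L_{f,c} - \bar L_{i,c})}:
#' mean elongation of each treatment as a percentage of the mean control
#' elongation. Records with final length below initial length are kept
#' (they simply contribute negative elongation) but counted in
#' `n_shrunk` for inspection.
#'
#' @param records Data.frame with columns `medium_label`, `as_total_uM`,
#'   `seed_id`, `length_initial_mm`, `length_final_mm`, `is_control`
#'   (logical; alternatively the control is taken as `as_total_uM == 0`).
#' @return A data.frame with one row per treatment: `medium_label`,
#'   `as_total_uM`, `n_seeds`, `n_shrunk`, `mean_elongation_mm`, `rre`.
#'   The control row has `rre = 100` by construction.
#' @export
#' @examples
#' rl <- data.frame(medium_label = "m", as_total_uM = rep(c(0, 10), each = 2),
#'                  seed_id = 1:4, length_initial_mm = 5,
#'                  length_final_mm = c(55, 65, 35, 25),
#'                  is_control = rep(c(TRUE, FALSE), each = 2))
#' compute_rre(rl)
compute_rre <- function(records) {
  need <- c("medium_label", "as_total_uM", "length_initial_mm", "length_final_mm")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(records$is_control)) records$is_control <- records$as_total_uM == 0
  records$elong <- records$length_final_mm - records$length_initial_mm
  ctrl <- records[records$is_control, ]
  if (!nrow(ctrl)) stop("no control group in records")
  ctrl_elong <- mean(ctrl$elong)
  if (ctrl_elong <= 0) stop("mean control elongation must be > 0")
  sp <- split(records, list(records$medium_label, records$as_total_uM),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(
      medium_label = d$medium_label[1],
      as_total_uM = d$as_total_uM[1],
      n_seeds = nrow(d),
      n_shrunk = sum(d$elong < 0),
      mean_elongation_mm = mean(d$elong),
      rre = 100 * mean(d$elong) / ctrl_elong
    )
  }))
  out <- out[order(out$as_total_uM), ]
  rownames(out) <- NULL
  out
}

#' Fit the four-parameter sigmoidal dose-response curve
#'
#' Nonlinear least squares of \eqn{y = y_0 + a / (1 + e^{-(x - x_0)/b})}
#' with y the observed effect (RRE, %) and x the natural log of the As(V)
#' activity (or concentration). Initialisation is deterministic:
#' y0 = min(y), a = max(y) - min(y), x0 = median(x), |b| = range(x)/6 with
#' the sign taken from the empirical y-x trend, so repeated fits of the
#' same data are identical. Non-convergence and degenerate inputs are
#' reported as errors, never silently worked around.
#'
#' @param x Numeric vector, ln activity (finite; drop the zero-dose
#'   control before fitting).
#' @param y Numeric vector of effects (%).
#' @return An object of class `logistic_fit`: list with `a`, `b`, `x0`,
#'   `y0`, `covariance` (4x4), `converged`, `fitted_fun(x)`, `x_range`.
#' @export
#' @examples
#' x <- log(c(0.5, 2, 10, 50, 200, 1000) * 1e-6)
#' y <- 100 / (1 + exp(-(x - log(4.5e-5)) / -0.5))
#' fit_dose_response(x, y)
fit_dose_response <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 5) stop("need >= 5 distinct finite x values")
  if (diff(range(y)) < sqrt(.Machine$double.eps)) {
    stop("constant response: dose-response fit is degenerate")
  }
  b0 <- diff(range(x)) / 6
  if (stats::cor(x, y) < 0) b0 <- -b0   # decreasing response
  start <- c(y0 = min(y), a = diff(range(y)), x0 = stats::median(x), b = b0)
  resid_fun <- function(p) {
    y - (p[["y0"]] + p[["a"]] / (1 + exp(-(x - p[["x0"]]) / p[["b"]])))
  }
  lm_fit <- tryCatch(
    minpack.lm::nls.lm(start, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("dose-response fit failed: ", conditionMessage(e))
  )
  # info codes 1:3 signal convergence of the Levenberg-Marquardt iteration
  if (!lm_fit$info %in% 1:3) {
    stop("dose-response fit failed: ", lm_fit$message)
  }
  cf <- lm_fit$par
  if (cf[["b"]] == 0) stop("degenerate fit: b = 0")
  # vcov = s^2 (J'J)^-1 with J'J from the solver's returned hessian
  vc <- tryCatch({
    s2 <- lm_fit$deviance / (length(x) - 4)
    v <- s2 * solve(lm_fit$hessian)
    dimnames(v) <- list(names(cf), names(cf))
    v
  }, error = function(e) matrix(NA_real_, 4, 4))
  structure(
    list(
      a = cf[["a"]], b = cf[["b"]], x0 = cf[["x0"]], y0 = cf[["y0"]],
      covariance = vc, converged = TRUE,
      fitted_fun = function(xx) cf[["y0"]] + cf[["a"]] /
        (1 + exp(-(xx - cf[["x0"]]) / cf[["b"]])),
      x_range = range(x)
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> y = %.3g + %.3g / (1 + exp(-(x - %.3g)/%.3g))\n",
    x$y0, x$a, x$x0, x$b))
  invisible(x)
}

# Solve y(x) = level on a logistic curve with the given parameters;
# returns NA when the curve does not cross the level between the bounds.
.solve_logistic_level <- function(y0, a, x0, b, level, lower, upper) {
  f <- function(xx) y0 + a / (1 + exp(-(xx - x0) / b)) - level
  flo <- f(lower); fhi <- f(upper)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NA_real_)
  stats::uniroot(f, c(lower, upper), tol = 1e-12)$root
}

#' EC50 from a fitted dose-response curve
#'
#' Solves y(x) = 50 (absolute percent of control, not the curve midpoint)
#' on the fitted curve within the observed x range, and returns exp(x) as
#' the EC50 activity. For a full-range curve (y0 = 0, a = 100) this
#' coincides with exp(x0). The standard deviation is a parametric
#' bootstrap: parameter draws from the fit's covariance, each solved for
#' its 50% crossing, under a fixed default seed so results are
#' reproducible.
#'
#' @param fit A `logistic_fit`.
#' @param n_boot Number of bootstrap draws (default 1000).
#' @param seed RNG seed for the bootstrap (default 20220208).
#' @param extend Fractional extension of the search interval beyond the
#'   observed x range (default 0.25; the crossing of a draw may sit
#'   slightly outside the data).
#' @return An `ec_estimate` with basis `"measured"`.
#' @export
ec50_from_fit <- function(fit, n_boot = 1000, seed = 20220208, extend = 0.25) {
  stopifnot(inherits(fit, "logistic_fit"))
  w <- diff(fit$x_range) * extend
  lo <- fit$x_range[1] - w; hi <- fit$x_range[2] + w
  xc <- .solve_logistic_level(fit$y0, fit$a, fit$x0, fit$b, 50, lo, hi)
  if (is.na(xc)) stop("fitted curve does not cross 50% within the data range")
  sdv <- NA_real_
  if (all(is.finite(fit$covariance)) && n_boot > 0) {
    mu <- c(fit$y0, fit$a, fit$x0, fit$b)
    vc <- fit$covariance
    ord <- match(c("y0", "a", "x0", "b"), rownames(vc))
    if (!anyNA(ord)) vc <- vc[ord, ord]
    draws <- withr_seed(seed, MASS::mvrnorm(n_boot, mu, vc))
    xs <- apply(draws, 1L, function(p)
      .solve_logistic_level(p[1], p[2], p[3], p[4], 50, lo, hi))
    xs <- xs[is.finite(xs)]
    if (length(xs) >= 0.5 * n_boot) sdv <- stats::sd(exp(xs))
  }
  ec_estimate(exp(xc), sd = sdv, basis = "measured")
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's RNG stream.
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a root-length assay table from CSV
#'
#' Columns `medium_label, as_total_uM, seed_id, length_initial_mm,
#' length_final_mm, is_control`.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_root_length_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(df$is_control)) df$is_control <- as.logical(df$is_control)
  df
}
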