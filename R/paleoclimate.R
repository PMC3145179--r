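#' Centered running mean of an isotope series
#'
#' Smooths values over `window` consecutive samples. Odd windows use the
#' plain centered mean; even windows use the standard symmetric centered
#' moving average (half weight on the two outermost of `window + 1`
#' samples, so the window is not shifted by half a sample). Points too
#' close to either end use the largest symmetric plain window that fits
#' (the "shrunken symmetric window" rule). The window is counted in
#' samples, not in Myr.
#'
#' @param series Data frame with columns `age_ma` and `d18o_permil` (or any
#'   second numeric column); rows are sorted by age internally.
#' @param window Positive integer, at most the series length.
#' @return The series with an added `d18o_smoothed` column, sorted by
#'   increasing age.
#' @export
running_mean <- function(series, window = 50) {
  stopifnot(is.data.frame(series), "age_ma" %in% names(series))
  valcol <- setdiff(names(series), "age_ma")[1]
  n <- nrow(series)
  if (window < 1) stop("window must be >= 1")
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")")
  o <- order(series$age_ma)
  series <- series[o, , drop = FALSE]
  x <- series[[valcol]]
  if (!all(is.finite(series$age_ma)) || !all(is.finite(x))) {
    stop("ages and values must be finite")
  }
  even <- window %% 2 == 0
  half <- if (even) window / 2 else (window - 1) / 2
  sm <- numeric(n)
  for (i in seq_len(n)) {
    if (i - half < 1 || i + half > n) {
      h <- min(i - 1, n - i)
      sm[i] <- mean(x[(i - h):(i + h)])
    } else if (even) {
      w <- c(0.5, rep(1, window - 1), 0.5)
      sm[i] <- sum(w * x[(i - half):(i + half)]) / window
    } else {
      sm[i] <- mean(x[(i - half):(i + half)])
    }
  }
  series$d18o_smoothed <- sm
  rownames(series) <- NULL
  series
}

#' Default Beringian calibration anchors
#'
#' Present-day mean annual temperature of -9 degC for relatively warm
#' Beringian localities, 4 degC at 9 Ma and 11 degC at 14 Ma.
#'
#' @return Data frame with columns `age_ma`, `temp_c`.
#' @export
default_anchors <- function() {
  data.frame(age_ma = c(0, 9, 14), temp_c = c(-9, 4, 11))
}

#' Calibrate a smoothed delta-18O series to Beringian temperature
#'
#' Builds the piecewise-linear map in delta-18O space through the anchor
#' pairs (smoothed delta-18O at each anchor age, anchor temperature),
#' extended linearly beyond the outermost anchors, and applies it pointwise.
#' By construction the curve reproduces every anchor temperature exactly; the
#' anchor ages are inserted into the output grid so that age-interpolation
#' also honours them exactly. A least-squares linear alternative is available
#' via `method = "linear_fit"`.
#'
#' @param smoothed Output of [running_mean()] (needs `age_ma` and
#'   `d18o_smoothed`).
#' @param anchors Data frame (`age_ma`, `temp_c`) with at least two rows and
#'   distinct ages, all within the series age span.
#' @param method `"anchor_exact"` (default) or `"linear_fit"`.
#' @return A data frame of class `paleo_curve` with columns `age_ma`,
#'   `d18o_smoothed`, `temp_c`, carrying the anchors and method as
#'   attributes.
#' @export
calibrate_paleocurve <- function(smoothed, anchors = default_anchors(),
                                 method = c("anchor_exact", "linear_fit")) {
  method <- match.arg(method)
  stopifnot(all(c("age_ma", "d18o_smoothed") %in% names(smoothed)))
  if (nrow(anchors) < 2) stop("at least two anchors are required")
  if (anyDuplicated(anchors$age_ma)) stop("anchor ages must be distinct")
  ages <- smoothed$age_ma
  span <- range(ages)
  if (any(anchors$age_ma < span[1] | anchors$age_ma > span[2])) {
    stop("anchor ages must lie within the series age span")
  }
  d_anchor <- stats::approx(ages, smoothed$d18o_smoothed,
                            xout = anchors$age_ma)$y
  if (method == "anchor_exact") {
    if (any(abs(diff(sort(d_anchor))) < 1e-12)) {
      stop("smoothed delta-18O values at the anchor ages coincide; ",
           "the delta-18O -> temperature map would be degenerate")
    }
    o <- order(d_anchor)
    dk <- d_anchor[o]; tk <- anchors$temp_c[o]
    temp_of_d <- function(d) {
      piecewise_linear(d, dk, tk)
    }
  } else {
    fit <- stats::lm(anchors$temp_c ~ d_anchor)
    temp_of_d <- function(d) unname(fit$coefficients[1] +
                                    fit$coefficients[2] * d)
  }
  add_ages <- setdiff(anchors$age_ma, ages)
  if (length(add_ages)) {
    extra <- data.frame(
      age_ma = add_ages,
      d18o_smoothed = stats::approx(ages, smoothed$d18o_smoothed,
                                    xout = add_ages)$y)
    base <- smoothed[, c("age_ma", "d18o_smoothed")]
    curve <- rbind(base, extra)
    curve <- curve[order(curve$age_ma), ]
  } else {
    curve <- smoothed[order(ages), c("age_ma", "d18o_smoothed")]
  }
  curve$temp_c <- temp_of_d(curve$d18o_smoothed)
  # pin the anchors exactly (guards against interpolation round-off)
  if (method == "anchor_exact") {
    hit <- match(anchors$age_ma, curve$age_ma)
    curve$temp_c[hit] <- anchors$temp_c
  }
  rownames(curve) <- NULL
  attr(curve, "anchors") <- anchors
  attr(curve, "method") <- method
  class(curve) <- c("paleo_curve", class(curve))
  curve
}

# Piecewise-linear interpolation through (xk, yk) knots with linear
# extension beyond the outermost knots; exact at the knots.
piecewise_linear <- function(x, xk, yk) {
  out <- numeric(length(x))
  k <- length(xk)
  for (i in seq_along(x)) {
    xi <- x[i]
    j <- match(TRUE, abs(xi - xk) < 1e-300)
    if (!is.na(j)) { out[i] <- yk[j]; next }
    if (xi <= xk[1]) {
      sl <- (yk[2] - yk[1]) / (xk[2] - xk[1])
      out[i] <- yk[1] + sl * (xi - xk[1])
    } else if (xi >= xk[k]) {
      sl <- (yk[k] - yk[k - 1]) / (xk[k] - xk[k - 1])
      out[i] <- yk[k] + sl * (xi - xk[k])
    } else {
      j <- findInterval(xi, xk)
      sl <- (yk[j + 1] - yk[j]) / (xk[j + 1] - xk[j])
      out[i] <- yk[j] + sl * (xi - xk[j])
    }
  }
  out
}

#' Temperature at a given age from a calibrated paleocurve
#'
#' Linear interpolation in age between the two bracketing curve samples.
#' Ages outside the curve span are an error: the curve is never silently
#' extrapolated.
#'
#' @param curve A `paleo_curve` from [calibrate_paleocurve()].
#' @param age Ma before present (vectorized).
#' @return Temperature(s) in degC.
#' @export
temp_at <- function(curve, age) {
  stopifnot(inherits(curve, "paleo_curve"))
  span <- range(curve$age_ma)
  if (any(age < span[1] | age > span[2])) {
    stop(sprintf("age outside the curve span [%g, %g] Ma", span[1], span[2]))
  }
  stats::approx(curve$age_ma, curve$temp_c, xout = age, ties = "ordered")$y
}
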