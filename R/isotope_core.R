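#' Convert an isotope abundance ratio to delta notation
#'
#' Expresses a sample's heavy/light isotope abundance ratio as the per-mil
#' deviation from a reference standard (VSMOW for water):
#' \eqn{\delta = (R_{sample}/R_{standard} - 1) \times 1000}.
#'
#' @param r_sample Sample abundance ratio(s) (e.g. D/H), must be >= 0.
#' @param r_standard Standard abundance ratio, must be > 0.
#' @return Delta value(s) in permil.
#' @examples
#' delta_from_ratio(0.9, 1)   # -100
#' delta_from_ratio(1.01, 1)  # +10
#' @export
delta_from_ratio <- function(r_sample, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop("invalid standard: r_standard must be finite and > 0")
  }
  if (any(!is.finite(r_sample)) || any(r_sample < 0)) {
    stop("r_sample must be finite and >= 0")
  }
  (r_sample / r_standard - 1) * 1000
}

#' Invert delta notation back to an abundance ratio
#'
#' @param delta Delta value(s) in permil.
#' @param r_standard Standard abundance ratio, must be > 0.
#' @return Abundance ratio(s).
#' @export
ratio_from_delta <- function(delta, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop("invalid standard: r_standard must be finite and > 0")
  }
  (delta / 1000 + 1) * r_standard
}

#' Deuterium excess
#'
#' d-excess = delta2H - 8 * delta18O, the deviation of a water sample from
#' the global meteoric water line (GMWL, dD = 8 d18O + 10). Points on the
#' GMWL have d-excess exactly 10 permil; evaporated waters fall below.
#'
#' @param d2H delta2H in permil VSMOW.
#' @param d18O delta18O in permil VSMOW.
#' @return d-excess in permil.
#' @examples
#' d_excess(-70, -10)  # 10: a GMWL point
#' @export
d_excess <- function(d2H, d18O) {
  if (any(!is.finite(d2H)) || any(!is.finite(d18O))) {
    stop("d2H and d18O must be finite")
  }
  d2H - 8 * d18O
}

#' Fit a meteoric water line by ordinary least squares
#'
#' Regresses delta2H on delta18O for precipitation samples, the standard
#' construction of a local meteoric water line (LMWL). Ordinary least
#' squares is used (not reduced major axis), matching how such lines are
#' conventionally reported alongside slope-below-8 interpretations.
#'
#' @param samples Data frame of isotope samples with columns `d2H_permil`
#'   and `d18O_permil`. If a `sample_type` column is present only rows with
#'   `sample_type == "precipitation"` are used.
#' @return An object of class `meteoric_line`: list with `slope`,
#'   `intercept` (permil), `r_squared`, `n`, `residual_sd` (permil).
#' @export
fit_meteoric_line <- function(samples) {
  if (!is.null(samples$sample_type)) {
    samples <- samples[samples$sample_type == "precipitation", , drop = FALSE]
  }
  x <- samples$d18O_permil
  y <- samples$d2H_permil
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("degenerate input: need >= 3 precipitation samples")
  if (stats::var(x) == 0) stop("degenerate input: zero d18O variance")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  out <- list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = 1 - ss_res / ss_tot,
    n = length(x),
    residual_sd = sqrt(ss_res / max(length(x) - 2, 1))
  )
  class(out) <- "meteoric_line"
  out
}

#' @export
print.meteoric_line <- function(x, ...) {
  cat(sprintf("Meteoric water line: dD = %.2f d18O %+.2f  (R^2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Default soil-layer source scheme
#'
#' The eight shallowest sampled depth intervals (0-5, 5-10, 10-20, 20-40,
#' 40-60, 60-80, 80-100, 100-120 cm) used as mixing-model sources. The
#' deepest sampled interval (120-150 cm) is generated by the synthetic
#' module but excluded from the default source set.
#'
#' @return Data frame with columns `layer`, `depth_top_cm`, `depth_bottom_cm`.
#' @export
default_layer_scheme <- function() {
  top <- c(0, 5, 10, 20, 40, 60, 80, 100)
  bottom <- c(5, 10, 20, 40, 60, 80, 100, 120)
  data.frame(
    layer = sprintf("%d-%d cm", top, bottom),
    depth_top_cm = top,
    depth_bottom_cm = bottom,
    stringsAsFactors = FALSE
  )
}

#' Default depth-group mapping
#'
#' Maps the eight source layers to the depth groups used for reporting:
#' 0-20 cm (herb main zone), 20-40 cm (semi-shrub), 40-100 cm (shrub), and
#' a separately reported 100-120 cm remainder.
#'
#' @return Named character vector: names are layer labels, values group labels.
#' @export
default_depth_groups <- function() {
  scheme <- default_layer_scheme()
  grp <- ifelse(scheme$depth_bottom_cm <= 20, "0-20 cm",
         ifelse(scheme$depth_bottom_cm <= 40, "20-40 cm",
         ifelse(scheme$depth_bottom_cm <= 100, "40-100 cm", "100-120 cm")))
  stats::setNames(grp, scheme$layer)
}

#' Summarize soil samples into per-layer source signatures
#'
#' Computes, for each layer of the scheme, the mean, standard deviation
#' (n-1 denominator) and count of both isotopes. These per-layer summaries
#' are the source signatures consumed by the mixing model. A sample is
#' assigned to the layer whose half-open interval \[top, bottom) contains
#' its depth midpoint; samples falling outside every layer (e.g. the
#' 120-150 cm interval under the default scheme) are dropped.
#'
#' Layers with a single replicate get SD 0 and are flagged in the
#' `sd_flagged` column rather than raising an error; the mixing model's
#' `sd_floor` guards against the resulting degenerate SDs.
#'
#' @param soil Data frame of soil samples with columns `depth_top_cm`,
#'   `depth_bottom_cm`, `d2H_permil`, `d18O_permil`.
#' @param scheme Layer scheme as returned by [default_layer_scheme()].
#' @return Data frame with one row per layer: `layer`, `depth_top_cm`,
#'   `depth_bottom_cm`, `n`, `mean_d2H`, `sd_d2H`, `mean_d18O`, `sd_d18O`,
#'   `sd_flagged`.
#' @export
summarize_sources <- function(soil, scheme = default_layer_scheme()) {
  if (!is.null(soil$sample_type)) {
    soil <- soil[soil$sample_type == "soil", , drop = FALSE]
  }
  mid <- (soil$depth_top_cm + soil$depth_bottom_cm) / 2
  out <- scheme
  out$n <- 0L
  out$mean_d2H <- out$sd_d2H <- out$mean_d18O <- out$sd_d18O <- NA_real_
  out$sd_flagged <- FALSE
  for (i in seq_len(nrow(scheme))) {
    in_layer <- mid >= scheme$depth_top_cm[i] & mid < scheme$depth_bottom_cm[i]
    n <- sum(in_layer)
    if (n == 0) {
      stop(sprintf("missing source: no soil samples in layer %s", scheme$layer[i]))
    }
    out$n[i] <- n
    out$mean_d2H[i] <- mean(soil$d2H_permil[in_layer])
    out$mean_d18O[i] <- mean(soil$d18O_permil[in_layer])
    if (n == 1) {
      out$sd_d2H[i] <- 0
      out$sd_d18O[i] <- 0
      out$sd_flagged[i] <- TRUE
    } else {
      out$sd_d2H[i] <- stats::sd(soil$d2H_permil[in_layer])
      out$sd_d18O[i] <- stats::sd(soil$d18O_permil[in_layer])
    }
  }
  if (any(out$sd_flagged)) {
    warning("single-replicate layer(s): SD reported as 0 for ",
            paste(out$layer[out$sd_flagged], collapse = ", "))
  }
  out
}
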