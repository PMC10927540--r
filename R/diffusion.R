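# Diffusion-coefficient estimation from punctual-labeling decay and FRAP
# recovery: shared per-frame Gaussian fitting kernel, width- and
# amplitude-based estimators, ensemble statistics.

# Analytic Jacobian columns for the isotropic Gaussian + background model
# value = bg + A * exp(-((x-cx)^2 + (y-cy)^2) / (2 v))
gauss_model_jacobian <- function(p, xg, yg) {
  e <- exp(-((xg - p["cx"])^2 + (yg - p["cy"])^2) / (2 * p["v"]))
  cbind(
    A = e,
    cx = p["A"] * e * (xg - p["cx"]) / p["v"],
    cy = p["A"] * e * (yg - p["cy"]) / p["v"],
    v = p["A"] * e * ((xg - p["cx"])^2 + (yg - p["cy"])^2) / (2 * p["v"]^2),
    bg = 1
  )
}

fit_gaussian_frame <- function(frame, pixel_size) {
  ny <- nrow(frame); nx <- ncol(frame)
  xg <- rep((seq_len(nx) - 0.5) * pixel_size, each = ny)
  yg <- rep((seq_len(ny) - 0.5) * pixel_size, times = nx)
  z <- as.vector(frame)
  # initialize from a blurred copy: moments on the raw noisy frame are
  # dominated by background fluctuations for faint/broad spots
  sm <- blur_norm(frame, 2)
  bg0 <- stats::median(sm)
  a0 <- max(sm) - bg0
  w <- as.vector(pmax(sm - bg0 - 0.2 * a0, 0))
  # flatness is judged on the blurred image against the blurred noise
  # level (pixel noise attenuated by the kernel area)
  sd_hf <- stats::sd(z - as.vector(sm))
  sd_sm <- sd_hf / sqrt(4 * pi * 2^2)
  flat <- sum(w) <= 0 || a0 <= 4 * sd_sm + 1e-9 * max(abs(z), 1)
  if (sum(w) > 0) {
    cx0 <- sum(w * xg) / sum(w)
    cy0 <- sum(w * yg) / sum(w)
    v0 <- max(sum(w * ((xg - cx0)^2 + (yg - cy0)^2)) / (2 * sum(w)),
              (0.5 * pixel_size)^2)
  } else {
    cx0 <- mean(xg); cy0 <- mean(yg); v0 <- pixel_size^2
  }
  p0 <- c(A = a0, cx = cx0, cy = cy0, v = v0, bg = bg0)
  resid_fun <- function(p) {
    p <- stats::setNames(p, names(p0))
    z - (p["bg"] + p["A"] *
           exp(-((xg - p["cx"])^2 + (yg - p["cy"])^2) / (2 * p["v"])))
  }
  fit <- try(minpack.lm::nls.lm(
    par = p0, fn = resid_fun,
    lower = c(-Inf, -Inf, -Inf, (0.25 * pixel_size)^2, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(data.frame(amplitude = NA, cx = NA, cy = NA, var = NA, bg = NA,
                      se_var = NA, se_amplitude = NA, converged = FALSE,
                      flat = flat))
  }
  p <- stats::setNames(stats::coef(fit), names(p0))
  J <- gauss_model_jacobian(p, xg, yg)
  s2 <- fit$deviance / max(length(z) - 5, 1)
  cv <- try(s2 * solve(crossprod(J)), silent = TRUE)
  ses <- if (inherits(cv, "try-error")) rep(NA_real_, 5) else sqrt(diag(cv))
  data.frame(amplitude = p[["A"]], cx = p[["cx"]], cy = p[["cy"]],
             var = p[["v"]], bg = p[["bg"]],
             se_var = ses[4], se_amplitude = ses[1],
             converged = fit$info %in% 1:4, flat = flat)
}

#' Fit a 2D Gaussian + background to every frame of a series
#'
#' Shared fitting kernel of the diffusion estimators: a least-squares
#' isotropic 2D Gaussian with constant background is fitted per frame.
#' Degenerate (flat) frames are flagged rather than fitted blindly.
#'
#' @param series An [image_series()].
#' @param roi Optional list with integer pixel ranges `rows` and `cols`
#'   restricting the fit region.
#' @return data.frame with one row per frame: `time`, `amplitude`, center
#'   (`cx`, `cy`, um), per-axis `var` (um^2), `bg`, standard errors and
#'   `converged` / `flat` flags.
#' @export
fit_gaussian_frames <- function(series, roi = NULL) {
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$frames)
  if (d[3] < 3) stop("need at least 3 frames")
  rows <- if (is.null(roi)) seq_len(d[1]) else roi$rows
  cols <- if (is.null(roi)) seq_len(d[2]) else roi$cols
  stopifnot(all(rows >= 1), all(rows <= d[1]),
            all(cols >= 1), all(cols <= d[2]))
  res <- do.call(rbind, lapply(seq_len(d[3]), function(k) {
    fit_gaussian_frame(series$frames[rows, cols, k], series$pixel_size)
  }))
  res <- cbind(frame = seq_len(d[3]), time = series$timestamps, res)
  if (mean(!res$converged) > 0.5) {
    stop("Gaussian fit failed to converge in more than half of the frames")
  }
  res
}

new_diffusion_fit <- function(D_hat, se, method, frames, n_used,
                              flags = character(0), D_both = NULL) {
  structure(list(D_hat = D_hat, se = se, method = method,
                 frames = frames, n_used = n_used, flags = flags,
                 D_both = D_both),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("Diffusion fit (%s): D = %.4g +/- %.2g um^2/s (%d frames)\n",
              x$method, x$D_hat, x$se, x$n_used))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) {
  c(D = object$D_hat)
}

# Width estimator: per-axis fitted variance grows as var0 + 2 D t;
# amplitude estimator: 1/peak is linear in t with slope/intercept = 2D/var0.
punctual_regressions <- function(fits) {
  ok <- fits$converged & !fits$flat & is.finite(fits$se_var) &
    fits$se_var > 0
  f <- fits[ok, , drop = FALSE]
  if (nrow(f) < 3) stop("fewer than 3 usable frames")
  wfit <- stats::lm(var ~ time, data = f, weights = 1 / f$se_var^2)
  slope <- stats::coef(wfit)[["time"]]
  # a numerically-zero slope counts as non-spreading
  if (abs(slope) < 1e-8 * stats::median(f$var) / diff(range(f$time))) {
    slope <- 0
  }
  se_slope <- summary(wfit)$coefficients["time", "Std. Error"]
  v0 <- stats::coef(wfit)[["(Intercept)"]]
  inv_a <- 1 / f$amplitude
  w_a <- f$amplitude^4 / f$se_amplitude^2
  afit <- stats::lm(inv_a ~ f$time, weights = w_a)
  b <- stats::coef(afit)[[2]]; a <- stats::coef(afit)[[1]]
  se_b <- summary(afit)$coefficients[2, "Std. Error"]
  list(
    D_width = slope / 2, se_width = se_slope / 2,
    D_amp = (b / a) * v0 / 2, se_amp = abs(se_b / a) * v0 / 2,
    n_used = nrow(f), slope = slope
  )
}

#' Estimate a diffusion coefficient from a punctual-labeling series
#'
#' The labeled spot spreads by free 2D diffusion, so its fitted per-axis
#' variance grows linearly with slope `2 D` (equivalently, its full width
#' squared grows as `4 D t` when width^2 is defined as twice the per-axis
#' variance) while its peak decays as `1 / (var0 + 2 D t)`. Both the
#' width-slope and amplitude-decay regressions are computed; the requested
#' one is reported, and a flag is raised if they disagree by more than
#' three joint standard errors.
#'
#' @param series An [image_series()] whose first frame follows the end of
#'   the labeling pulse.
#' @param roi Optional pixel ROI (see [fit_gaussian_frames()]).
#' @param method `"punctual_width"` (default) or `"punctual_amplitude"`.
#' @return A `diffusion_fit` with `D_hat` (um^2/s), standard error, the
#'   per-frame fit table and flags. A non-spreading series yields
#'   `D_hat = 0` with a warning.
#' @export
estimate_diffusivity_punctual <- function(series, roi = NULL,
                                          method = c("punctual_width",
                                                     "punctual_amplitude")) {
  method <- match.arg(method)
  fits <- fit_gaussian_frames(series, roi)
  reg <- punctual_regressions(fits)
  flags <- character(0)
  disagree <- abs(reg$D_width - reg$D_amp) /
    sqrt(reg$se_width^2 + reg$se_amp^2)
  if (is.finite(disagree) && disagree > 3) flags <- c(flags, "method_disagreement")
  D <- if (method == "punctual_width") reg$D_width else reg$D_amp
  se <- if (method == "punctual_width") reg$se_width else reg$se_amp
  if (reg$slope <= 0) {
    warning("variance series is non-increasing: no detectable spreading",
            call. = FALSE)
    D <- 0
    flags <- c(flags, "no_spreading")
  }
  new_diffusion_fit(max(D, 0), se, method, fits, reg$n_used, flags,
                    D_both = c(width = reg$D_width, amplitude = reg$D_amp))
}

#' Estimate a diffusion coefficient from a FRAP series
#'
#' The prebleach frames establish the fluorescence plateau; post-bleach
#' frames are inverted into an evolving Gaussian hole (depth and variance
#' vs time) and analyzed with the same width-slope regression as the
#' punctual estimator, sign inverted.
#'
#' @param series A [generate_frap_series()]-style [image_series()] whose
#'   prebleach frames carry negative timestamps.
#' @param roi Optional pixel ROI.
#' @param method Reported regression, as in
#'   [estimate_diffusivity_punctual()].
#' @return A `diffusion_fit` with method `"frap_recovery"`. If the hole
#'   has already filled between the first two post-bleach frames, the fit
#'   is flagged `"lower_bound"`.
#' @export
estimate_diffusivity_frap <- function(series, roi = NULL,
                                      method = c("punctual_width",
                                                 "punctual_amplitude")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "image_series"))
  pre <- series$timestamps < 0
  if (!any(pre)) stop("no prebleach frames: plateau cannot be established")
  d <- dim(series$frames)
  plateau <- mean(series$frames[, , pre])
  post_idx <- which(!pre)
  # negative values (plateau noise) are kept: flooring would bias the wings
  hole <- array(plateau - series$frames[, , post_idx, drop = FALSE],
                c(d[1], d[2], length(post_idx)))
  # hole detection on smoothed images so shot noise does not mimic a hole
  pre_idx <- which(pre)
  noise_sd_sm <- stats::sd(blur_norm(series$frames[, , pre_idx[1]], 2) -
                             plateau)
  if (max(blur_norm(hole[, , 1], 2)) < 5 * noise_sd_sm) {
    stop("no detectable bleach hole")
  }
  noise_sd <- stats::sd(series$frames[, , pre])
  hole <- hole - min(hole)  # uniform shift absorbed by the background term
  hole_series <- image_series(hole, series$pixel_size,
                              series$frame_interval, channel = "frap-hole",
                              timestamps = series$timestamps[post_idx])
  fits <- fit_gaussian_frames(hole_series, roi)
  reg <- punctual_regressions(fits)
  flags <- character(0)
  # resolution limit: hole depth indistinguishable from noise by frame 2
  if (fits$amplitude[2] < 3 * noise_sd) flags <- c(flags, "lower_bound")
  D <- if (method == "punctual_width") reg$D_width else reg$D_amp
  se <- if (method == "punctual_width") reg$se_width else reg$se_amp
  if (reg$slope <= 0) {
    warning("hole variance series is non-increasing: no detectable recovery")
    D <- 0
    flags <- c(flags, "no_recovery")
  }
  new_diffusion_fit(max(D, 0), se, "frap_recovery", fits, reg$n_used,
                    flags, D_both = c(width = reg$D_width,
                                      amplitude = reg$D_amp))
}

#' Ensemble statistics over replicate diffusion fits
#'
#' @param fits List of `diffusion_fit` objects (>= 2).
#' @return Object of class `diffusion_ensemble` with `n`, `mean` and the
#'   sample `sd` of the `D_hat` values. A warning is raised if the fits mix
#'   estimation methods.
#' @export
ensemble_stats <- function(fits) {
  stopifnot(is.list(fits), all(vapply(fits, inherits, logical(1),
                                      "diffusion_fit")))
  if (length(fits) < 2) stop("need at least 2 fits for ensemble statistics")
  methods <- vapply(fits, function(f) f$method, character(1))
  if (length(unique(methods)) > 1) {
    warning("mixed estimation methods in one ensemble")
  }
  d <- vapply(fits, function(f) f$D_hat, numeric(1))
  structure(list(n = length(d), mean = mean(d), sd = stats::sd(d),
                 D = d, methods = unique(methods)),
            class = "diffusion_ensemble")
}

#' @export
print.diffusion_ensemble <- function(x, ...) {
  cat(sprintf("Diffusion ensemble: n = %d, D = %.4g +/- %.4g um^2/s (%s)\n",
              x$n, x$mean, x$sd, paste(x$methods, collapse = ", ")))
  invisible(x)
}

#' Export a diffusion fit as JSON (per-frame table as CSV)
#'
#' @param fit A `diffusion_fit`.
#' @param path Output JSON path; the per-frame table is written next to it
#'   with a `-frames.csv` suffix.
#' @export
write_diffusion_fit <- function(fit, path) {
  stopifnot(inherits(fit, "diffusion_fit"))
  jsonlite::write_json(
    list(D_hat = fit$D_hat, se = fit$se, method = fit$method,
         n_used = fit$n_used, flags = fit$flags),
    path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(fit$frames, sub("\\.json$", "-frames.csv", path),
                   row.names = FALSE)
  invisible(path)
}
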