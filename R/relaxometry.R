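# Voxelwise mono-exponential T2 estimation from multi-echo magnitude data.
# Default estimator: unweighted log-linear least squares on all echoes;
# a signal-domain nonlinear least-squares refinement (optionally with a
# constant offset) is available for bias studies.

#' Multi-echo image container
#'
#' @param echoes List of numeric matrices (one magnitude image per echo),
#'   all on the same grid.
#' @param echo_train Strictly increasing echo times in ms, one per echo.
#' @param voxel_spacing In-plane voxel size in mm.
#' @return An object of class \code{multi_echo_image}.
#' @export
multi_echo_image <- function(echoes, echo_train, voxel_spacing = 1) {
  stopifnot(is.list(echoes), length(echoes) == length(echo_train),
            length(echo_train) >= 3L, all(diff(echo_train) > 0))
  shp <- dim(echoes[[1]])
  ok <- vapply(echoes, function(e) identical(dim(e), shp), logical(1))
  if (!all(ok)) stop("all echo images must share one grid shape", call. = FALSE)
  structure(list(echoes = echoes, echo_train = as.numeric(echo_train),
                 voxel_spacing = voxel_spacing, grid_shape = shp),
            class = "multi_echo_image")
}

#' @export
print.multi_echo_image <- function(x, ...) {
  cat(sprintf("<multi_echo_image> %d echoes, grid %d x %d, TE %s ms\n",
              length(x$echoes), x$grid_shape[1], x$grid_shape[2],
              paste(signif(x$echo_train, 4), collapse = ", ")))
  invisible(x)
}

# Shared signal preparation: zero and negative samples (impossible for true
# magnitudes but present in synthetic edge cases) are clipped to a small
# floor relative to the voxel's peak so logs are defined; positive samples
# are never altered.
clip_signal <- function(signal, floor_frac = 1e-6) {
  peak <- max(signal, 0)
  if (peak <= 0) {
    return(list(signal = signal, n_clipped = length(signal), peak = 0))
  }
  clipped <- signal <= 0
  signal[clipped] <- floor_frac * peak
  list(signal = signal, n_clipped = sum(clipped), peak = peak)
}

#' Log-linear mono-exponential T2 fit for one voxel
#'
#' Straight-line least squares of log(signal) against echo time:
#' log S = log S0 - TE / T2, so T2 = -1 / slope and S0 = exp(intercept).
#' Non-positive samples are clipped to 1e-6 of the voxel's peak before the
#' log; voxels with more than two clipped echoes, fewer than three echoes,
#' or a non-decaying fit (slope >= 0) are flagged invalid rather than
#' raising an error.
#'
#' @param signal Numeric vector of magnitudes, one per echo.
#' @param echo_train Echo times in ms, same length as \code{signal}.
#' @param max_clipped Maximum clipped echoes tolerated before the fit is
#'   marked invalid (default 2).
#' @return List with \code{t2} (ms), \code{s0}, \code{r2} (coefficient of
#'   determination of the log-domain line), \code{valid}, \code{n_clipped}.
#' @export
#' @examples
#' te <- default_echo_train()
#' fit_t2_loglinear(1000 * exp(-te / 28.1), te)$t2
fit_t2_loglinear <- function(signal, echo_train, max_clipped = 2L) {
  stopifnot(length(signal) == length(echo_train), length(signal) >= 3L)
  cl <- clip_signal(signal)
  if (cl$peak <= 0) {
    return(list(t2 = NA_real_, s0 = NA_real_, r2 = NA_real_,
                valid = FALSE, n_clipped = cl$n_clipped))
  }
  y <- log(cl$signal)
  x <- echo_train
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  slope <- sum((x - xm) * (y - ym)) / sxx
  intercept <- ym - slope * xm
  res <- y - (intercept + slope * x)
  sst <- sum((y - ym)^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  valid <- is.finite(slope) && slope < 0 && cl$n_clipped <= max_clipped
  list(t2 = if (valid) -1 / slope else NA_real_,
       s0 = if (valid) exp(intercept) else NA_real_,
       r2 = r2, valid = valid, n_clipped = cl$n_clipped)
}

#' Nonlinear least-squares T2 fit for one voxel
#'
#' Levenberg-Marquardt fit of S0 * exp(-TE / T2) (optionally plus a constant
#' offset C, useful when a noise floor or baseline contaminates the decay)
#' in the signal domain.  Initialization defaults to the log-linear
#' solution; on non-convergence the log-linear result is returned with
#' \code{fallback = TRUE}.
#'
#' @inheritParams fit_t2_loglinear
#' @param init Optional list or vector with elements \code{t2} and
#'   \code{s0} used as the starting point.
#' @param offset If \code{TRUE}, fit S0 * exp(-TE/T2) + C.
#' @return List with \code{t2}, \code{s0}, \code{r2} (signal-domain),
#'   \code{valid}, \code{fallback}, and \code{offset_value} (NA unless
#'   \code{offset}).
#' @export
fit_t2_nls <- function(signal, echo_train, init = NULL, offset = FALSE) {
  stopifnot(length(signal) == length(echo_train), length(signal) >= 3L)
  ll <- fit_t2_loglinear(signal, echo_train)
  if (is.null(init)) {
    if (!ll$valid) {
      return(list(t2 = ll$t2, s0 = ll$s0, r2 = ll$r2, valid = FALSE,
                  fallback = TRUE, offset_value = NA_real_))
    }
    init <- list(t2 = ll$t2, s0 = ll$s0)
  } else {
    init <- as.list(init)
  }
  df <- data.frame(s = signal, te = echo_train)
  start <- if (offset) {
    list(s0 = init$s0, t2 = init$t2, c0 = 0)
  } else {
    list(s0 = init$s0, t2 = init$t2)
  }
  form <- if (offset) s ~ s0 * exp(-te / t2) + c0 else s ~ s0 * exp(-te / t2)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start,
                      lower = if (offset) c(0, 0.1, -Inf) else c(0, 0.1),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(t2 = ll$t2, s0 = ll$s0, r2 = ll$r2, valid = ll$valid,
                fallback = TRUE, offset_value = NA_real_))
  }
  co <- stats::coef(fit)
  res <- stats::resid(fit)
  sst <- sum((signal - mean(signal))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  list(t2 = unname(co["t2"]), s0 = unname(co["s0"]), r2 = r2,
       valid = is.finite(co["t2"]) && co["t2"] > 0,
       fallback = FALSE,
       offset_value = if (offset) unname(co["c0"]) else NA_real_)
}

#' Compute a voxelwise T2 map from a multi-echo image
#'
#' Applies the chosen per-voxel mono-exponential fit inside \code{mask}
#' (or over the whole grid).  The log-linear method is evaluated in closed
#' form over all voxels at once; results are identical to looping
#' \code{\link{fit_t2_loglinear}} voxel by voxel.
#'
#' @param image A \code{\link{multi_echo_image}}.
#' @param mask Optional logical matrix on the image grid (or a
#'   \code{\link{tendon_mask}}) selecting voxels to fit.
#' @param method \code{"loglinear"} (default) or \code{"nls"}.
#' @param exclude_first_echo Drop the first echo before fitting (stimulated
#'   echoes commonly contaminate it on real acquisitions).
#' @return An object of class \code{t2_map}: matrices \code{t2}, \code{s0},
#'   \code{r2}, logical \code{valid}, plus the echo train and method.  All
#'   fields are NA (and \code{valid} FALSE) outside the fitted voxels.
#' @export
compute_t2_map <- function(image, mask = NULL,
                           method = c("loglinear", "nls"),
                           exclude_first_echo = FALSE) {
  stopifnot(inherits(image, "multi_echo_image"))
  method <- match.arg(method)
  shp <- image$grid_shape
  if (inherits(mask, "tendon_mask")) mask <- mask$voxels
  if (is.null(mask)) {
    mask <- matrix(TRUE, shp[1], shp[2])
  }
  if (!identical(dim(mask), shp)) {
    stop("mask grid does not match the image grid", call. = FALSE)
  }
  keep_echo <- if (exclude_first_echo) -1L else seq_along(image$echo_train)
  tes <- image$echo_train[keep_echo]
  if (length(tes) < 3L) stop("need at least 3 echoes after exclusion", call. = FALSE)

  t2 <- s0 <- r2 <- matrix(NA_real_, shp[1], shp[2])
  valid <- matrix(FALSE, shp[1], shp[2])
  idx <- which(mask)
  if (length(idx)) {
    S <- vapply(image$echoes[keep_echo], function(e) e[idx],
                numeric(length(idx)))
    S <- matrix(S, nrow = length(idx))
    if (method == "loglinear") {
      peak <- apply(S, 1, max)
      dead <- peak <= 0
      clipped <- S <= 0
      Sc <- ifelse(clipped, pmax(peak, 0) * 1e-6, S)
      n_clip <- rowSums(clipped)
      Y <- log(Sc)
      Y[dead, ] <- NA
      xm <- mean(tes)
      xc <- tes - xm
      sxx <- sum(xc^2)
      ym <- rowMeans(Y)
      slope <- as.vector(Y %*% xc) / sxx
      icept <- ym - slope * xm
      fitted <- outer(icept, rep(1, length(tes))) + outer(slope, tes)
      ssr <- rowSums((Y - fitted)^2)
      sst <- rowSums((Y - ym)^2)
      r2v <- ifelse(sst > 0, 1 - ssr / sst, NA_real_)
      ok <- !dead & is.finite(slope) & slope < 0 & n_clip <= 2
      t2[idx] <- ifelse(ok, -1 / slope, NA_real_)
      s0[idx] <- ifelse(ok, exp(icept), NA_real_)
      r2[idx] <- r2v
      valid[idx] <- ok
    } else {
      for (k in seq_along(idx)) {
        f <- fit_t2_nls(S[k, ], tes)
        t2[idx[k]] <- f$t2; s0[idx[k]] <- f$s0; r2[idx[k]] <- f$r2
        valid[idx[k]] <- isTRUE(f$valid)
      }
    }
  }
  structure(list(t2 = t2, s0 = s0, r2 = r2, valid = valid,
                 echo_train = tes, method = method,
                 voxel_spacing = image$voxel_spacing),
            class = "t2_map")
}

#' @export
print.t2_map <- function(x, ...) {
  cat(sprintf("<t2_map> %d x %d, %d valid voxels, method %s\n",
              nrow(x$t2), ncol(x$t2), sum(x$valid), x$method))
  if (any(x$valid)) {
    cat(sprintf("  T2 range (valid): %.1f - %.1f ms\n",
                min(x$t2[x$valid]), max(x$t2[x$valid])))
  }
  invisible(x)
}
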