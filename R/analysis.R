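# Trajectory, polarity, morphology and path-choice statistics. All functions
# are pure functions of the track table (or state), so re-analysis is
# bit-reproducible.

.track_dt <- function(track) {
  dt <- diff(track$t)
  if (length(dt) == 0) stop("track has fewer than 2 frames")
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("track sampling is not uniform")
  dt[1]
}

#' Time-averaged mean-square displacement
#'
#' `MSD(tau) = < |r(t + tau) - r(t)|^2 >_t` over all start frames, for the
#' requested lags.
#'
#' @param track data.frame with columns `t`, `x`, `y` (uniform sampling).
#' @param lags lag times (s), multiples of the sampling interval; default
#'   every available lag up to a quarter of the track duration.
#' @return data.frame with `tau`, `msd` and the number of averaged pairs `n`.
#' @export
msd <- function(track, lags = NULL) {
  dt <- .track_dt(track)
  n <- nrow(track)
  if (is.null(lags)) lags <- dt * seq_len(max(1, floor((n - 1) / 4)))
  ks <- unique(round(lags / dt))
  ks <- ks[ks >= 1 & ks <= n - 1]
  out <- lapply(ks, function(k) {
    dx <- track$x[(1 + k):n] - track$x[1:(n - k)]
    dy <- track$y[(1 + k):n] - track$y[1:(n - k)]
    data.frame(tau = k * dt, msd = mean(dx^2 + dy^2), n = n - k)
  })
  do.call(rbind, out)
}

#' Fit the MSD scaling exponent
#'
#' Least-squares fit of `log(MSD)` against `log(tau)` (`MSD = A * tau^alpha`)
#' over an optional lag window.
#'
#' @param m data.frame from [msd()] (or any `tau`/`msd` table).
#' @param tau_range length-2 lag window (s); default all lags.
#' @return list with `alpha`, `A`, standard error `se` and the number of
#'   lags used.
#' @export
fitMsdExponent <- function(m, tau_range = NULL) {
  if (!is.null(tau_range))
    m <- m[m$tau >= tau_range[1] & m$tau <= tau_range[2], , drop = FALSE]
  m <- m[m$msd > 0, , drop = FALSE]
  if (nrow(m) < 2) return(list(alpha = NA_real_, A = NA_real_,
                               se = NA_real_, n = nrow(m)))
  fit <- lm(log(msd) ~ log(tau), data = m)
  cf <- coef(fit)
  se <- suppressWarnings(unname(sqrt(diag(vcov(fit)))[2]))
  list(alpha = unname(cf[2]), A = exp(unname(cf[1])), se = se, n = nrow(m))
}

#' Circular standard deviation
#'
#' `sqrt(-2 * log(Rbar))` with `Rbar` the mean resultant length of the
#' angles; the standard directional-statistics dispersion, bounded behaviour
#' at high dispersion.
#'
#' @param theta angles (radians).
#' @return circular standard deviation (radians).
#' @export
circularSd <- function(theta) {
  theta <- theta[is.finite(theta)]
  if (!length(theta)) return(NA_real_)
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  sqrt(-2 * log(max(rbar, .Machine$double.eps)))
}

#' Windowed local MSD exponent and directedness classification
#'
#' Splits the track into non-overlapping windows of length `window`, fits the
#' local MSD scaling exponent `alpha` per window (`dR^2(t_i, tau_k) = A *
#' tau_k^alpha`, lags from the sampling interval up to `window * lag_frac`),
#' computes the circular standard deviation `dphi` of the frame-to-frame
#' velocity angles, and labels the window `directed` when `alpha >
#' alpha_min` and `dphi < dphi_max`, else `random`. A zero-displacement
#' window has an undefined exponent: it is labelled `random` and flagged.
#'
#' @param track data.frame with `t`, `x`, `y`.
#' @param window window length (s); default 300.
#' @param lag_frac largest fitted lag as a fraction of the window; default
#'   1/3.
#' @param alpha_min,dphi_max classification thresholds (1.7 and 0.9 rad).
#' @return data.frame with one row per window: `ti` (window start), `alpha`,
#'   `A`, `dphi`, `label`, `flagged`.
#' @export
localAlpha <- function(track, window = 300, lag_frac = 1 / 3,
                       alpha_min = 1.7, dphi_max = 0.9) {
  dt <- .track_dt(track)
  per <- max(2, round(window / dt))
  if (per < 10) warning("fewer than 10 samples per window")
  n <- nrow(track)
  nw <- floor((n - 1) / per)
  if (nw < 1) stop("track shorter than one window")
  out <- lapply(seq_len(nw), function(w) {
    idx <- ((w - 1) * per + 1):(w * per + 1)
    sub <- track[idx, , drop = FALSE]
    m <- msd(sub, lags = dt * seq_len(max(1, floor(per * lag_frac))))
    flagged <- all(m$msd < 1e-12)
    a <- if (flagged) list(alpha = NA_real_, A = NA_real_)
         else fitMsdExponent(m)
    ang <- atan2(diff(sub$y), diff(sub$x))
    step <- sqrt(diff(sub$x)^2 + diff(sub$y)^2)
    dphi <- circularSd(ang[step > 1e-12])
    directed <- !flagged && is.finite(a$alpha) && is.finite(dphi) &&
      a$alpha > alpha_min && dphi < dphi_max
    data.frame(ti = sub$t[1], alpha = a$alpha, A = a$A, dphi = dphi,
               label = if (directed) "directed" else "random",
               flagged = flagged)
  })
  do.call(rbind, out)
}

#' Directional persistence length of a trajectory
#'
#' Tangent-correlation estimator: the mean cosine of the heading change over
#' contour distance `s` is fitted to `exp(-s / Lp)`. The fit uses the
#' contiguous initial range of separations where the correlation stays above
#' `cmin` (log-linear least squares through the origin). A non-decaying
#' correlation (straight path) cannot bound `Lp` from above: the total path
#' length is returned as a lower bound with attribute `lower_bound = TRUE`.
#'
#' @param track data.frame with `t`, `x`, `y` (at least 100 frames).
#' @param cmin smallest correlation used in the fit.
#' @param max_frac largest step separation considered, as a fraction of the
#'   number of steps.
#' @return persistence length (um), possibly with attribute `lower_bound`.
#' @export
persistenceLength <- function(track, cmin = 0.2, max_frac = 0.25) {
  if (nrow(track) < 100) stop("need at least 100 frames")
  dx <- diff(track$x)
  dy <- diff(track$y)
  step <- sqrt(dx^2 + dy^2)
  keep <- step > 1e-12
  phi <- atan2(dy[keep], dx[keep])
  ns <- length(phi)
  if (ns < 10) stop("trajectory is numerically stationary")
  ds <- mean(step[keep])
  path_len <- sum(step)
  kmax <- max(2, floor(ns * max_frac))
  corr <- vapply(seq_len(kmax), function(k) {
    mean(cos(phi[(1 + k):ns] - phi[1:(ns - k)]))
  }, numeric(1))
  s <- ds * seq_len(kmax)
  # contiguous initial run above the correlation floor
  below <- which(corr <= cmin)
  kfit <- if (length(below)) below[1] - 1 else kmax
  if (kfit < 1) {
    # correlation lost within one step: persistence at the single-step scale
    c1 <- max(corr[1], 1e-3)
    return(-s[1] / log(c1))
  }
  slope <- sum(s[1:kfit] * log(corr[1:kfit])) / sum(s[1:kfit]^2)
  if (slope >= -1e-12) {
    out <- path_len
    attr(out, "lower_bound") <- TRUE
    return(out)
  }
  lp <- -1 / slope
  if (lp > path_len) {
    out <- path_len
    attr(out, "lower_bound") <- TRUE
    return(out)
  }
  lp
}

#' Polarity angle between migration direction and the nucleus-centrosome axis
#'
#' `theta(t)` is the angle between the centroid velocity (central
#' differences) and the vector from the nucleus centre to the centrosome;
#' `theta < 90` degrees means the centrosome leads, `theta > 90` degrees
#' that it trails. Frames with speed below `v_floor` are excluded.
#'
#' @param track data.frame with `t`, `x`, `y`, `cx`, `cy`, `nx`, `ny`.
#' @param v_floor minimum speed (um/s) for a frame to be included.
#' @return data.frame with `t` and `theta` (degrees in `[0, 180]`).
#' @export
polarityAngle <- function(track, v_floor = 1e-3) {
  n <- nrow(track)
  if (n < 3) stop("need at least 3 frames")
  dt <- .track_dt(track)
  i <- 2:(n - 1)
  vx <- (track$x[i + 1] - track$x[i - 1]) / (2 * dt)
  vy <- (track$y[i + 1] - track$y[i - 1]) / (2 * dt)
  ax <- track$cx[i] - track$nx[i]
  ay <- track$cy[i] - track$ny[i]
  sp <- sqrt(vx^2 + vy^2)
  al <- sqrt(ax^2 + ay^2)
  ok <- sp >= v_floor & al > 1e-12
  cosang <- pmin(1, pmax(-1, (vx * ax + vy * ay) / (sp * al)))
  data.frame(t = track$t[i][ok], theta = acos(cosang[ok]) * 180 / pi)
}

#' Cell morphology metrics of a state
#'
#' Area by the shoelace formula, area ratio relative to the initial disc
#' `pi * Rcell^2`, aspect ratio `sqrt(lambda1 / lambda2)` of the
#' membrane-bead gyration tensor, and distances of the nucleus centre and
#' centrosome from the cell centroid.
#'
#' @param st a `cellState` (or any list with `membrane`, `nucleus`,
#'   `centrosome`).
#' @param Rcell initial cell radius (um) for the area ratio.
#' @return list with `area`, `area_ratio`, `aspect_ratio`, `d_nuc_center`,
#'   `d_cen_center`.
#' @export
morphology <- function(st, Rcell = 7) {
  m <- st$membrane
  n <- nrow(m)
  j <- c(2:n, 1)
  area <- abs(sum(m[, 1] * m[j, 2] - m[j, 1] * m[, 2]) / 2)
  cen <- colMeans(m)
  d <- sweep(m, 2, cen)
  g <- crossprod(d) / n
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  aspect <- sqrt(ev[1] / max(ev[2], 1e-300))
  nc <- colMeans(st$nucleus)
  list(area = area, area_ratio = area / (pi * Rcell^2), aspect_ratio = aspect,
       d_nuc_center = sqrt(sum((nc - cen)^2)),
       d_cen_center = sqrt(sum((st$centrosome - cen)^2)))
}

#' Channel-choice statistics over replicate runs
#'
#' @param entries data.frame with one row per run: `channel` (label, `NA` if
#'   the run never entered a channel) and `time` (first entry time, s).
#' @param labels optional vector of all channel labels (so channels entered
#'   by no run appear with fraction 0).
#' @return list with `fractions` (per channel plus `censored`; sums to 1),
#'   `n`, and `entry_time` (mean, sd and count among entrants).
#' @export
channelChoiceStats <- function(entries, labels = NULL) {
  stopifnot(is.data.frame(entries), "channel" %in% names(entries))
  n <- nrow(entries)
  if (is.null(labels)) labels <- sort(unique(entries$channel[!is.na(entries$channel)]))
  counts <- vapply(labels, function(l) sum(entries$channel == l, na.rm = TRUE),
                   numeric(1))
  censored <- sum(is.na(entries$channel))
  fr <- c(counts, censored = censored) / n
  et <- entries$time[!is.na(entries$channel)]
  list(fractions = fr, n = n,
       entry_time = list(mean = if (length(et)) mean(et) else NA_real_,
                         sd = if (length(et) > 1) sd(et) else NA_real_,
                         n = length(et)))
}
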