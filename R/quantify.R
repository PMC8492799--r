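## Quantification chain: SPGR inversion to concentration, dual-sequence
## merge, sinus VIF extraction and voxel-wise Patlak fitting.

#' Convert dynamic signal to contrast-agent concentration
#'
#' Inverts the spoiled gradient-echo signal equation per voxel. The baseline
#' signal S0 is the mean of the pre-contrast volumes; together with the
#' pre-contrast T1 it fixes the voxel's scaling factor, after which
#' `E1(t) = (k - S) / (k - S cos a)` yields `R1(t)` and
#' `C(t) = (R1(t) - 1/T10) / r1`. Negative concentrations from noise are
#' retained (the histogram noise correction depends on them). Voxels with
#' non-positive S0 or T10 are flagged invalid (NA); samples whose signal
#' exceeds the invertible range are clamped and counted.
#'
#' @param series a [dynamicSeries()] from a single sequence.
#' @param t1map 3D array of pre-contrast T1 (s); voxels with `t10 <= 0` are
#'   treated as outside the head.
#' @param protocol an [acquisitionProtocol()].
#' @param linearized if `TRUE`, use the first-order approximation
#'   `C = RE / (r1 * T10 * f)` (with `f` the baseline saturation factor)
#'   instead of the full SPGR inversion.
#' @return A [concentrationSeries()] with a `qc` attribute: list with
#'   `nInvalid` (voxels excluded) and `nClamped` (samples clamped).
#' @export
concentrationFromSignal <- function(series, t1map, protocol,
                                    linearized = FALSE) {
  validObject(series)
  d <- dim(series@data)
  if (!identical(d[1:3], dim(t1map)))
    stop("series and t1map must share one grid")
  nvox <- prod(d[1:3]); nvol <- d[4]
  mat <- matrix(series@data, nrow = nvox, ncol = nvol)
  t10 <- as.numeric(t1map)
  s0 <- rowMeans(mat[, seq_len(series@baselineCount), drop = FALSE])
  invalid <- !(is.finite(s0) & s0 > 0 & is.finite(t10) & t10 > 0)

  a <- protocol@flipAngle * pi / 180
  conc <- matrix(NA_real_, nrow = nvox, ncol = nvol)
  nClamped <- 0L
  ok <- which(!invalid)
  if (length(ok)) {
    e10 <- exp(-protocol@tr / t10[ok])
    if (linearized) {
      ## d S / d R1 at baseline gives S = S0 (1 + f * TR * r1 * C * ...):
      ## RE = (S - S0)/S0 ~ C * r1 * TR * f with
      ## f = E10 (1 - cos a) / ((1 - E10)(1 - cos a E10))
      f <- e10 * (1 - cos(a)) / ((1 - e10) * (1 - cos(a) * e10))
      re <- mat[ok, , drop = FALSE] / s0[ok] - 1
      conc[ok, ] <- re / (protocol@r1Relaxivity * protocol@tr * f)
    } else {
      k <- s0[ok] * (1 - cos(a) * e10) / (1 - e10)   # = m0 sin(a) per voxel
      s <- mat[ok, , drop = FALSE]
      e1 <- (k - s) / (k - s * cos(a))
      bad <- !is.finite(e1) | e1 <= 0 | e1 >= 1
      ## S = 0 gives E1 = 1 exactly (C at the natural floor); only E1 <= 0
      ## (signal beyond model range) is a genuine clamp.
      nClamped <- sum(!is.finite(e1) | e1 <= 0)
      e1[bad] <- pmin(pmax(e1[bad], 1e-8), 1 - 1e-12)
      r1 <- -log(e1) / protocol@tr
      conc[ok, ] <- (r1 - 1 / t10[ok]) / protocol@r1Relaxivity
    }
  }
  out <- concentrationSeries(
    array(conc, dim = d), series@times,
    provenance = rep(series@sequenceTag, nvol),
    baseline = seq_len(nvol) <= series@baselineCount)
  attr(out, "qc") <- list(nInvalid = sum(invalid), nClamped = nClamped)
  out
}

#' Merge the fast and slow dynamic sequences
#'
#' Chronologically merges the two concentration (or signal) series acquired
#' at different temporal resolutions into a single series with per-volume
#' sequence provenance. Each sequence's pre-contrast baseline volumes are
#' retained (flagged); after setting baselines aside, every fast volume must
#' precede every slow volume — overlapping post-contrast time ranges are an
#' error.
#'
#' @param fast,slow two [concentrationSeries()] objects on the same grid (a
#'   `slow` series with zero volumes is allowed and returns `fast`
#'   unchanged).
#' @return A merged [concentrationSeries()], times strictly increasing.
#' @export
mergeDualSequences <- function(fast, slow) {
  if (!is(fast, "ConcentrationSeries") || !is(slow, "ConcentrationSeries"))
    stop("mergeDualSequences expects two ConcentrationSeries")
  if (length(slow@times) == 0L) return(fast)
  if (!identical(dim(fast@conc)[1:3], dim(slow@conc)[1:3]))
    stop("fast and slow series must share one grid")
  fPost <- fast@times[!fast@baseline]
  sPost <- slow@times[!slow@baseline]
  if (length(fPost) && length(sPost) && max(fPost) >= min(sPost)) {
    off <- which(!fast@baseline & fast@times >= min(sPost))
    stop("post-baseline time ranges overlap: fast volumes ",
         paste(off, collapse = ", "), " at or after first slow volume")
  }
  times <- c(fast@times, slow@times)
  if (anyDuplicated(times)) stop("duplicate timestamps across sequences")
  ord <- order(times)
  d <- dim(fast@conc)[1:3]
  nvox <- prod(d)
  conc <- cbind(matrix(fast@conc, nrow = nvox),
                matrix(slow@conc, nrow = nvox))[, ord, drop = FALSE]
  concentrationSeries(
    array(conc, dim = c(d, length(times))), times[ord],
    provenance = c(fast@provenance, slow@provenance)[ord],
    baseline = c(fast@baseline, slow@baseline)[ord])
}

#' Extract the vascular input function from the sagittal sinus
#'
#' Averages the concentration over the sinus voxels at each time point of
#' the merged dual-resolution grid to obtain the whole-blood curve `cb(t)`,
#' converts it to plasma concentration `cp = cb / (1 - Hct)`, and computes
#' the running integral of Cp by the trapezoid rule (on `max(cp, 0)`, so the
#' integral is non-decreasing under symmetric baseline noise).
#'
#' @param fast,slow [concentrationSeries()] objects for the two sequences
#'   (or pass an already-merged series as `fast` and `NULL` as `slow`).
#' @param sinusMask logical or 0/1 3D array selecting sinus voxels.
#' @param hematocrit blood hematocrit fraction.
#' @return A `VascularInputFunction` object.
#' @export
extractVif <- function(fast, slow, sinusMask, hematocrit = 0.45) {
  merged <- if (is.null(slow)) fast else mergeDualSequences(fast, slow)
  idx <- which(as.logical(sinusMask))
  if (length(idx) == 0L) stop("sinus mask is empty")
  if (is.unsorted(merged@times, strictly = TRUE))
    stop("merged times must be strictly increasing")
  d <- dim(merged@conc)
  mat <- matrix(merged@conc, nrow = prod(d[1:3]), ncol = d[4])
  cb <- colMeans(mat[idx, , drop = FALSE])
  cp <- cb / (1 - hematocrit)
  new("VascularInputFunction", times = merged@times, cb = cb, cp = cp,
      hematocrit = hematocrit,
      integral = as.numeric(pracma::cumtrapz(merged@times, pmax(cp, 0))))
}

#' Voxel-wise Patlak fit of the leakage transfer constant
#'
#' Fits the Patlak graphical linearization by ordinary least squares in each
#' in-mask voxel: `Ct(t)/Cp(t)` regressed on `integral(Cp, 0..t)/Cp(t)` over
#' the fit window. The slope, converted to min^-1, is the leakage transfer
#' constant Ki; the intercept is the plasma volume fraction vp. Negative
#' slopes are preserved — the downstream histogram noise correction requires
#' the full signed Ki distribution. Volumes flagged as baseline, outside the
#' fit window, or with plasma concentration at or below `cpFloor` are
#' excluded from the design.
#'
#' @param conc merged [concentrationSeries()].
#' @param vif a `VascularInputFunction` on the same time grid.
#' @param tissueMask logical or 0/1 3D array of voxels to fit.
#' @param fitWindow `c(start, end)` in seconds; default starts at the first
#'   post-baseline slow volume (after the bolus first pass, where the Patlak
#'   well-mixed assumption holds) and runs to the end of the acquisition.
#' @param cpFloor minimum plasma concentration (mmol/L) for a volume to
#'   enter the fit; guards the division by Cp.
#' @return A `KiMap` (slots `ki` min^-1, `vp`, `r2`, `nPoints`, `qc`).
#' @export
patlakFit <- function(conc, vif, tissueMask, fitWindow = NULL,
                      cpFloor = 1e-3) {
  if (!isTRUE(all.equal(conc@times, vif@times)))
    stop("concentration series and VIF must share one time grid")
  if (is.null(fitWindow)) {
    slowPost <- conc@times[conc@provenance == "slow" & !conc@baseline]
    fitWindow <- c(if (length(slowPost)) min(slowPost) else min(conc@times),
                   Inf)
  }
  sel <- which(!conc@baseline &
               conc@times >= fitWindow[1] & conc@times <= fitWindow[2] &
               vif@cp > cpFloor)
  if (length(sel) < 3L)
    stop("fewer than 3 usable time points in the fit window ",
         "(check cpFloor and fitWindow)")
  d <- dim(conc@conc)
  idx <- which(as.logical(tissueMask))
  mat <- matrix(conc@conc, nrow = prod(d[1:3]), ncol = d[4])
  x <- vif@integral[sel] / vif@cp[sel]
  y <- mat[idx, sel, drop = FALSE] / rep(vif@cp[sel], each = length(idx))

  fitted <- is.finite(rowSums(y))
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx <= 0) stop("rank-deficient Patlak design (constant abscissa)")
  ym <- rowMeans(y)
  yc <- y - ym
  slope <- as.numeric(yc %*% xc) / sxx        # per second
  intercept <- ym - slope * mean(x)
  ss <- rowSums(yc^2)
  r2 <- ifelse(ss > 0, slope^2 * sxx / ss, NA_real_)
  slope[!fitted] <- NA_real_
  intercept[!fitted] <- NA_real_
  r2[!fitted] <- NA_real_

  mk <- function(v) {
    arr <- array(NA_real_, dim = d[1:3]); arr[idx] <- v; arr
  }
  new("KiMap", ki = mk(slope * 60), vp = mk(intercept), r2 = mk(r2),
      nPoints = length(sel),
      qc = list(nVoxels = length(idx), nInvalid = sum(!fitted),
                fitWindow = c(min(conc@times[sel]), max(conc@times[sel])),
                cpFloor = cpFloor))
}

#' Run the full quantification chain on a simulated or loaded acquisition
#'
#' Convenience composition: signal-to-concentration conversion for both
#' sequences, dual-sequence merge, sinus VIF extraction and voxel-wise
#' Patlak fit over the four tissue regions.
#'
#' @param acq a list with `fast`, `slow`, `t1`, `labels` as returned by
#'   [simulateAcquisition()] or [readAcquisition()].
#' @param protocol an [acquisitionProtocol()].
#' @param ... passed on to [patlakFit()].
#' @return A list with `kiMap` (a `KiMap`), `vif`, `merged` and `qc`.
#' @export
quantifyKi <- function(acq, protocol, ...) {
  concFast <- concentrationFromSignal(acq$fast, acq$t1, protocol)
  concSlow <- concentrationFromSignal(acq$slow, acq$t1, protocol)
  merged <- mergeDualSequences(concFast, concSlow)
  vif <- extractVif(merged, NULL, acq$labels == regionCodes()[["SSS"]],
                    hematocrit = protocol@hematocrit)
  tissue <- acq$labels %in% regionCodes()[tissueRegions()]
  kiMap <- patlakFit(merged, vif, array(tissue, dim = dim(acq$labels)), ...)
  list(kiMap = kiMap, vif = vif, merged = merged,
       qc = list(fast = attr(concFast, "qc"), slow = attr(concSlow, "qc"),
                 fit = kiMap@qc))
}
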