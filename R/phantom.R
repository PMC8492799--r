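## Digital phantom: parametric vascular input function, Patlak forward
## model, SPGR signal generation and full dual-sequence acquisition.

#' Default parameters of the parametric vascular input function
#'
#' Gamma-variate first pass (peak, time-to-peak, shape) followed by a
#' biexponential washout with a smooth onset, on the plasma-concentration
#' scale of a standard-dose gadobutrol bolus.
#'
#' @return Named list of shape parameters (mmol/L and s^-1 units).
#' @export
defaultVifParams <- function() {
  list(peak = 6.0, tp = 10, alpha = 3,
       washAmp = c(2.0, 0.8), washRate = c(0.02, 0.0025), onsetRate = 0.1)
}

#' Generate a parametric vascular input function
#'
#' Builds a causal plasma-concentration curve Cp(t) standing in for the
#' measured superior-sagittal-sinus input function. Three shapes are
#' available: `"gammaBiexp"` (gamma-variate upslope plus biexponential
#' washout; the realistic default), `"biexponential"` (pure multi-exponential
#' decay from injection, closed-form integrable), and `"boxcar"` (constant
#' `c0` over `[tStart, tEnd]`).
#'
#' @param shape one of `"gammaBiexp"`, `"biexponential"`, `"boxcar"`.
#' @param params named list of shape parameters; see [defaultVifParams()]
#'   for `"gammaBiexp"`; `"biexponential"` takes `amp` and `rate` vectors;
#'   `"boxcar"` takes `c0`, `tStart`, `tEnd`.
#' @param injectionTime bolus injection time (s); Cp is exactly 0 before it.
#' @return A vectorized function `cp(t)` returning plasma concentration
#'   (mmol/L), with the shape, parameters and injection time attached as
#'   attributes.
#' @export
generateVif <- function(shape = c("gammaBiexp", "biexponential", "boxcar"),
                        params = NULL, injectionTime = 0) {
  shape <- match.arg(shape)
  if (is.null(params))
    params <- switch(shape,
      gammaBiexp = defaultVifParams(),
      biexponential = list(amp = c(3.0, 1.0), rate = c(0.02, 0.002)),
      boxcar = list(c0 = 1, tStart = injectionTime, tEnd = injectionTime + 60))
  vals <- unlist(params)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("VIF shape parameters must be finite and non-negative")
  if (!is.finite(injectionTime)) stop("injectionTime must be finite")
  fun <- switch(shape,
    gammaBiexp = function(t) {
      tau <- t - injectionTime
      out <- numeric(length(t))
      on <- tau > 0
      tauo <- tau[on]
      g <- params$peak * (tauo / params$tp)^params$alpha *
        exp(params$alpha * (1 - tauo / params$tp))
      w <- (1 - exp(-params$onsetRate * tauo)) *
        colSums(params$washAmp * exp(-outer(params$washRate, tauo)))
      out[on] <- g + w
      out
    },
    biexponential = function(t) {
      tau <- t - injectionTime
      out <- numeric(length(t))
      on <- tau >= 0            # jump at injection: right-continuous
      out[on] <- colSums(params$amp * exp(-outer(params$rate, tau[on])))
      out
    },
    boxcar = function(t) {
      ifelse(t >= params$tStart & t <= params$tEnd, params$c0, 0)
    })
  structure(fun, shape = shape, params = params,
            injectionTime = injectionTime, class = c("vifFunction", "function"))
}

## Dense cumulative integral of a Cp(t) function over [t0, tmax].
vifCumulativeIntegral <- function(vif, tmax, t0 = 0, dt = 0.05) {
  grid <- seq(min(t0, 0), tmax, by = dt)
  if (grid[length(grid)] < tmax) grid <- c(grid, tmax)
  cp <- vif(grid)
  list(times = grid, cp = cp,
       integral = as.numeric(pracma::cumtrapz(grid, cp)))
}

#' Patlak forward model: tissue concentration from a plasma input
#'
#' Computes the tissue concentration of a one-directional-transfer system,
#' `Ct(t) = (Ki/60) * integral(Cp, 0..t) + vp * Cp(t)`, with Ki in min^-1,
#' times in seconds and concentrations in mmol/L. This is the forward model
#' whose graphical (Patlak) linearization is fitted by [patlakFit()].
#'
#' @param vif a causal plasma-concentration function as returned by
#'   [generateVif()].
#' @param ki leakage transfer constant (min^-1), >= 0.
#' @param vp plasma volume fraction in `[0, 1)`.
#' @param times sample times (s), sorted ascending.
#' @param dt step of the internal quadrature grid (s).
#' @return Numeric vector of tissue concentration (mmol/L) at `times`.
#' @export
forwardTissueConcentration <- function(vif, ki, vp, times, dt = 0.05) {
  if (!is.function(vif)) stop("vif must be a function of time")
  if (!is.finite(ki) || ki < 0) stop("ki must be finite and >= 0")
  if (!is.finite(vp) || vp < 0 || vp >= 1) stop("vp must lie in [0, 1)")
  if (is.unsorted(times)) stop("times must be sorted ascending")
  dense <- vifCumulativeIntegral(vif, max(times), t0 = min(times), dt = dt)
  intAt <- stats::approx(dense$times, dense$integral, xout = times,
                         yleft = 0, rule = 2)$y
  (ki / 60) * intAt + vp * vif(times)
}

#' Spoiled gradient-echo steady-state signal
#'
#' Signal of a spoiled gradient-echo sequence at longitudinal relaxation rate
#' `R1(C) = 1/t10 + r1 * C`:
#' `S = m0 * sin(a) * (1 - E1) / (1 - cos(a) * E1)` with
#' `E1 = exp(-TR * R1)`. Strictly increasing in concentration for flip
#' angles in (0, 90] degrees. T2*/TE decay is absorbed into `m0` (it cancels
#' in the relative-enhancement analysis).
#'
#' @param concentration contrast concentration (mmol/L), vectorized.
#' @param t10 pre-contrast T1 (s), scalar or vector recycled over voxels.
#' @param protocol an [acquisitionProtocol()].
#' @param m0 equilibrium magnetization scale (arbitrary units).
#' @return Signal in arbitrary units, same shape as `concentration`.
#' @export
spgrSignal <- function(concentration, t10, protocol, m0 = 1) {
  if (any(t10 <= 0)) stop("t10 must be positive")
  if (any(concentration < 0, na.rm = TRUE))
    stop("concentration must be non-negative")
  a <- protocol@flipAngle * pi / 180
  r1 <- 1 / t10 + protocol@r1Relaxivity * concentration
  e1 <- exp(-protocol@tr * r1)
  m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

## Deterministic region label assignment: a seeded permutation of voxel
## indices sliced into per-region blocks.
assignLabels <- function(config) {
  n <- prod(config@gridShape)
  fr <- config@regionFractions
  counts <- round(fr * n)
  if (any(fr > 0 & counts < 1L))
    stop("grid too small to honor regionFractions: ",
         paste(names(fr)[fr > 0 & counts < 1L], collapse = ", "))
  if (sum(counts) > n)
    stop("grid too small to honor regionFractions (rounded counts exceed grid)")
  codes <- regionCodes()
  labels <- integer(n)
  perm <- sample.int(n)
  at <- 1L
  for (reg in names(fr)) {
    if (counts[[reg]] == 0L) next
    idx <- perm[at:(at + counts[[reg]] - 1L)]
    labels[idx] <- codes[[reg]]
    at <- at + counts[[reg]]
  }
  array(labels, dim = config@gridShape)
}

#' Simulate a dual-time-resolution DCE-MRI acquisition
#'
#' Generates the full synthetic study input: a fast dynamic series sampling
#' the bolus first pass, a slow series capturing the late subtle enhancement,
#' a pre-contrast T1 map and integer region masks, together with the ground
#' truth used by recovery tests. The slow sequence's pre-contrast baseline
#' volumes are placed before the fast block (negative times), matching an
#' acquisition in which both sequences image before bolus injection. Sinus
#' voxels carry whole-blood concentration `(1 - Hct) * Cp`; tissue voxels
#' follow the Patlak forward model with the configured Ki and vp. Zero-mean
#' Gaussian noise of standard deviation `noiseSD` is added on the signal
#' scale and the magnitude signal clamped at zero.
#'
#' @param config a [phantomConfig()].
#' @param protocol an [acquisitionProtocol()].
#' @param vifShape,vifParams shape specification passed to [generateVif()];
#'   injection time comes from `protocol@injectionDelay`.
#' @param downsampleFast if `TRUE`, mimic the coarser in-plane resolution of
#'   the fast sequence by 2x2 in-plane block averaging (grid preserved).
#' @return A list with elements `fast` and `slow` ([dynamicSeries()]), `t1`
#'   (3D array, s; 0 outside the head), `labels` (3D integer array coded
#'   background 0, NAWM 1, WMH 2, CGM 3, DGM 4, SSS 5), and `truth` (list:
#'   `kiMap`, `vpMap`, `t10Map`, `labels`, `vifTimes`, `vifCp`, `vif`).
#' @export
simulateAcquisition <- function(config, protocol,
                                vifShape = "gammaBiexp",
                                vifParams = defaultVifParams(),
                                downsampleFast = FALSE) {
  validObject(config); validObject(protocol)
  set.seed(config@seed)
  labels <- assignLabels(config)
  codes <- regionCodes()
  n <- prod(config@gridShape)

  fastTimes <- (seq_len(protocol@fastVolumes) - 0.5) * protocol@fastDST
  nSlowPost <- protocol@slowVolumes - protocol@slowBaseline
  slowTimes <- c(
    if (protocol@slowBaseline > 0)
      -(protocol@slowBaseline - seq_len(protocol@slowBaseline) + 0.5) *
        protocol@slowDST,
    protocol@fastVolumes * protocol@fastDST +
      (seq_len(nSlowPost) - 0.5) * protocol@slowDST)

  vif <- generateVif(vifShape, vifParams,
                     injectionTime = protocol@injectionDelay)

  ## Per-region concentration curves at each sequence's sample times.
  regionConc <- function(times) {
    out <- matrix(0, nrow = length(codes), ncol = length(times),
                  dimnames = list(names(codes), NULL))
    for (reg in names(config@regionFractions)) {
      if (reg == "SSS") {
        out[reg, ] <- (1 - protocol@hematocrit) * vif(times)
      } else {
        out[reg, ] <- forwardTissueConcentration(
          vif, config@kiTrue[[reg]], config@vpTrue[[reg]], times)
      }
    }
    out
  }

  buildSeries <- function(times, tag, baselineCount) {
    conc <- regionConc(times)
    sig <- matrix(0, nrow = length(codes), ncol = length(times),
                  dimnames = list(names(codes), NULL))
    for (reg in names(config@regionFractions))
      sig[reg, ] <- spgrSignal(conc[reg, ], config@t10[[reg]], protocol,
                               m0 = config@m0)
    dat <- sig[labels + 1L, ]          # voxel x volume lookup by label code
    if (config@noiseSD > 0)
      dat <- pmax(dat + rnorm(length(dat), 0, config@noiseSD), 0)
    dynamicSeries(array(dat, dim = c(config@gridShape, length(times))),
                  times, tag, baselineCount)
  }

  fast <- buildSeries(fastTimes, "fast", protocol@fastBaseline)
  slow <- buildSeries(slowTimes, "slow", max(protocol@slowBaseline, 1L))
  if (downsampleFast)
    fast <- dynamicSeries(blockAverageInPlane(fast@data), fast@times,
                          "fast", fast@baselineCount)

  lut <- function(values, default = 0) {
    v <- rep(default, length(codes)); names(v) <- names(codes)
    v[names(values)] <- values
    array(v[labels + 1L], dim = config@gridShape)
  }
  t10Map <- lut(config@t10)
  truth <- list(
    kiMap = lut(config@kiTrue), vpMap = lut(config@vpTrue),
    t10Map = t10Map, labels = labels,
    vifTimes = sort(unique(c(fastTimes, slowTimes))),
    vif = vif)
  truth$vifCp <- vif(truth$vifTimes)

  list(fast = fast, slow = slow, t1 = t10Map, labels = labels, truth = truth)
}

## 2x2 in-plane block average, result replicated back onto the input grid so
## that masks remain valid (a crude stand-in for the fast sequence's coarser
## in-plane voxels).
blockAverageInPlane <- function(data) {
  d <- dim(data)
  out <- data
  xs <- seq(1L, d[1] - 1L, by = 2L)
  ys <- seq(1L, d[2] - 1L, by = 2L)
  for (x in xs) for (y in ys) {
    blk <- (data[x, y, , , drop = FALSE] + data[x + 1L, y, , , drop = FALSE] +
            data[x, y + 1L, , , drop = FALSE] +
            data[x + 1L, y + 1L, , , drop = FALSE]) / 4
    out[x, y, , ] <- blk
    out[x + 1L, y, , ] <- blk
    out[x, y + 1L, , ] <- blk
    out[x + 1L, y + 1L, , ] <- blk
  }
  out
}
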