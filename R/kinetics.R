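# Single-cycle kinetics: 1:1 Langmuir simulation (closed form, piecewise
# per injection) and nonlinear least-squares fitting with multi-start
# initialisation.

#' KineticsModel: 1:1 Langmuir binding parameters
#'
#' @slot kon Association rate constant, 1/(M s).
#' @slot koff Dissociation rate constant, 1/s.
#' @slot Rmax Analyte binding capacity of the surface, response units.
#' @name KineticsModel-class
#' @aliases KineticsModel
#' @exportClass KineticsModel
setClass("KineticsModel",
  representation(kon = "numeric", koff = "numeric", Rmax = "numeric"))

setValidity("KineticsModel", function(object) {
  if (object@kon <= 0 || object@koff <= 0 || object@Rmax <= 0)
    "kon, koff and Rmax must all be > 0" else TRUE
})

#' @describeIn KineticsModel-class Constructor.
#' @param kon,koff,Rmax See slots.
#' @export
kineticsModel <- function(kon, koff, Rmax)
  new("KineticsModel", kon = kon, koff = koff, Rmax = Rmax)

#' @describeIn KineticsModel-class Equilibrium dissociation constant
#'   `KD = koff / kon` (M).
#' @param object A `KineticsModel`.
#' @export
KD <- function(object) object@koff / object@kon

setMethod("show", "KineticsModel", function(object) {
  cat(sprintf(
    "KineticsModel: kon %.4g 1/(M s), koff %.4g 1/s, KD %.4g M, Rmax %.4g RU\n",
    object@kon, object@koff, KD(object), object@Rmax))
})

#' InjectionProtocol: a single-cycle kinetics injection schedule
#'
#' Sequential injections of increasing analyte concentration without
#' regeneration, followed by one final dissociation phase.
#'
#' @slot concentrations Strictly ascending analyte concentrations, M.
#' @slot contactTime Association time per injection, s.
#' @slot finalDissociationTime Dissociation time after the last
#'   injection, s.
#' @slot interInjectionGap Buffer-flow gap between injections, s
#'   (default 0: instrument-specific and usually negligible).
#' @slot samplingRate Sensorgram sampling rate, Hz.
#' @name InjectionProtocol-class
#' @aliases InjectionProtocol
#' @exportClass InjectionProtocol
setClass("InjectionProtocol",
  representation(
    concentrations = "numeric",
    contactTime = "numeric",
    finalDissociationTime = "numeric",
    interInjectionGap = "numeric",
    samplingRate = "numeric"
  )
)

setValidity("InjectionProtocol", function(object) {
  msg <- character()
  if (length(object@concentrations) < 1L ||
      any(object@concentrations <= 0) ||
      is.unsorted(object@concentrations, strictly = TRUE))
    msg <- c(msg, "concentrations must be strictly ascending and > 0")
  if (object@contactTime <= 0 || object@finalDissociationTime <= 0 ||
      object@samplingRate <= 0)
    msg <- c(msg, "times and sampling rate must be > 0")
  if (object@interInjectionGap < 0)
    msg <- c(msg, "interInjectionGap must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "InjectionProtocol", function(object) {
  cat(sprintf(paste0(
    "InjectionProtocol: %d injections, %.3g-%.3g M, contact %.0f s, ",
    "final dissociation %.0f s, %.2g Hz\n"),
    length(object@concentrations), min(object@concentrations),
    max(object@concentrations), object@contactTime,
    object@finalDissociationTime, object@samplingRate))
})

#' Build a single-cycle kinetics protocol from a dilution series
#'
#' Defaults reproduce the canonical schedule: a 1 uM top concentration
#' with six 3-fold dilutions (seven solutions, 1 uM down to 1.37 nM),
#' 230 s contact time and 1,800 s final dissociation.
#'
#' @param topConc Highest concentration, M.
#' @param nInjections Number of injections.
#' @param dilution Serial dilution factor (> 1).
#' @param contactTime,finalDissociationTime,interInjectionGap,samplingRate
#'   See [InjectionProtocol-class].
#' @return An [InjectionProtocol] with ascending concentrations
#'   `topConc / dilution^(n-1), ..., topConc`.
#' @examples
#' makeSckProtocol()
#' @export
makeSckProtocol <- function(topConc = 1e-6, nInjections = 7L, dilution = 3,
                            contactTime = 230, finalDissociationTime = 1800,
                            interInjectionGap = 0, samplingRate = 1) {
  if (topConc <= 0) stop("topConc must be > 0")
  n <- .assertCount(nInjections, "nInjections")
  if (dilution <= 1) stop("dilution must be > 1")
  conc <- topConc / dilution^(seq.int(n - 1L, 0L))
  new("InjectionProtocol",
      concentrations = conc, contactTime = contactTime,
      finalDissociationTime = finalDissociationTime,
      interInjectionGap = interInjectionGap, samplingRate = samplingRate)
}

#' Sensorgram: a simulated or observed SCK trace
#'
#' @slot time Strictly increasing time grid, s.
#' @slot response Response, RU.
#' @slot protocol The [InjectionProtocol] the trace was produced under.
#' @name Sensorgram-class
#' @aliases Sensorgram
#' @exportClass Sensorgram
setClass("Sensorgram",
  representation(time = "numeric", response = "numeric",
                 protocol = "InjectionProtocol"))

setValidity("Sensorgram", function(object) {
  msg <- character()
  if (length(object@time) != length(object@response))
    msg <- c(msg, "time and response must have equal length")
  if (is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "time must be strictly increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Sensorgram", function(object) {
  cat(sprintf("Sensorgram: %d points over %.0f s, peak %.2f RU\n",
              length(object@time), max(object@time),
              max(object@response)))
})

#' @describeIn Sensorgram-class Time grid accessor.
#' @param x A `Sensorgram`.
#' @export
sensorTime <- function(x) x@time

#' @describeIn Sensorgram-class Response accessor.
#' @export
sensorResponse <- function(x) x@response

#' @describeIn Sensorgram-class Protocol accessor.
#' @export
sensorProtocol <- function(x) x@protocol

# segment boundaries of a protocol: data.frame(t0, t1, conc)
#' @noRd
.protocolSegments <- function(protocol) {
  conc <- protocol@concentrations
  segs <- list()
  t0 <- 0
  for (i in seq_along(conc)) {
    segs[[length(segs) + 1L]] <- c(t0, t0 + protocol@contactTime, conc[i])
    t0 <- t0 + protocol@contactTime
    if (protocol@interInjectionGap > 0 && i < length(conc)) {
      segs[[length(segs) + 1L]] <- c(t0, t0 + protocol@interInjectionGap, 0)
      t0 <- t0 + protocol@interInjectionGap
    }
  }
  segs[[length(segs) + 1L]] <- c(t0, t0 + protocol@finalDissociationTime, 0)
  out <- do.call(rbind, segs)
  data.frame(t0 = out[, 1L], t1 = out[, 2L], conc = out[, 3L])
}

# noiseless closed-form response on an arbitrary time grid
#' @noRd
.langmuirResponse <- function(kon, koff, Rmax, protocol, times) {
  segs <- .protocolSegments(protocol)
  resp <- numeric(length(times))
  R0 <- 0
  for (i in seq_len(nrow(segs))) {
    C <- segs$conc[i]
    kobs <- kon * C + koff
    Req <- if (C > 0) kon * C * Rmax / kobs else 0
    inSeg <- times >= segs$t0[i] &
      (times < segs$t1[i] | i == nrow(segs) & times <= segs$t1[i])
    dt <- times[inSeg] - segs$t0[i]
    resp[inSeg] <- Req + (R0 - Req) * exp(-kobs * dt)
    R0 <- Req + (R0 - Req) * exp(-kobs * (segs$t1[i] - segs$t0[i]))
  }
  resp
}

#' Simulate a single-cycle kinetics sensorgram
#'
#' Within each constant-concentration segment the 1:1 Langmuir model has
#' the closed form `R(t) = Req + (R0 - Req) exp(-(kon C + koff) t)` with
#' `Req = kon C Rmax / (kon C + koff)`; dissociation segments use `C = 0`.
#' The segment-end response carries over as the next segment's `R0` (no
#' regeneration). Gaussian noise of standard deviation `noiseSd` is added
#' when positive; the result is seed-deterministic.
#'
#' @param model A [KineticsModel].
#' @param protocol An [InjectionProtocol].
#' @param noiseSd Noise standard deviation, RU.
#' @param seed Integer seed used when `noiseSd > 0`.
#' @return A [Sensorgram].
#' @examples
#' simulateSck(kineticsModel(1e5, 1e-3, 100), makeSckProtocol())
#' @export
simulateSck <- function(model, protocol, noiseSd = 0, seed = 1L) {
  validObject(model); validObject(protocol)
  total <- nrow(.protocolSegments(protocol))
  tEnd <- .protocolSegments(protocol)$t1[total]
  times <- seq(0, tEnd, by = 1 / protocol@samplingRate)
  resp <- .langmuirResponse(model@kon, model@koff, model@Rmax, protocol,
                            times)
  if (noiseSd > 0) {
    set.seed(seed)
    resp <- resp + rnorm(length(resp), sd = noiseSd)
  }
  new("Sensorgram", time = times, response = resp, protocol = protocol)
}

#' Fit a 1:1 single-cycle kinetics model to a sensorgram
#'
#' Nonlinear least squares over `(kon, koff, Rmax)` in log10 space, with
#' multi-start initialisation on a grid spanning log10 kon in [3, 7] and
#' log10 koff in [-5, -1] (plus a data-driven Rmax start). The best start
#' by residual sum of squares wins; ties break towards the lower koff.
#' A fitted koff below 1e-5 1/s is flagged `koff_below_limit` - the
#' practical dissociation-rate floor of the instrument.
#'
#' @param sensorgram A [Sensorgram].
#' @param protocol Injection protocol (defaults to the sensorgram's).
#' @param konGrid,koffGrid Multi-start grids (log10).
#' @return A list with elements `model` ([KineticsModel]), `KD`, `se`
#'   (approximate standard errors of log10 kon / log10 koff / log10 Rmax),
#'   `rss`, `converged`, and `flags` (`koff_below_limit`). On non-finite
#'   residuals, a failure report (`converged = FALSE`) is returned rather
#'   than an exception.
#' @examples
#' sg <- simulateSck(kineticsModel(1e5, 1e-3, 100), makeSckProtocol())
#' fitSck(sg)$KD
#' @export
fitSck <- function(sensorgram, protocol = sensorProtocol(sensorgram),
                   konGrid = c(3, 5, 7), koffGrid = c(-5, -3, -1)) {
  times <- sensorgram@time
  obs <- sensorgram@response
  resid <- function(p) {
    r <- obs - .langmuirResponse(10^p[1L], 10^p[2L], 10^p[3L], protocol,
                                 times)
    r[!is.finite(r)] <- 1e6
    r
  }
  rmaxStart <- log10(max(max(obs), 1e-3) * 1.2)
  best <- NULL
  for (lk in konGrid) {
    for (lo in koffGrid) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = c(lk, lo, rmaxStart), fn = resid,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss - 1e-9 ||
          (abs(rss - best$rss) <= 1e-9 && fit$par[2L] < best$par[2L])) {
        best <- list(fit = fit, rss = rss, par = fit$par)
      }
    }
  }
  if (is.null(best))
    return(list(model = NULL, KD = NA_real_, se = NULL, rss = NA_real_,
                converged = FALSE, flags = character(0)))
  p <- best$par
  se <- tryCatch({
    h <- best$fit$hessian
    s2 <- best$rss / max(1L, length(obs) - 3L)
    sqrt(diag(solve(h)) * 2 * s2)
  }, error = function(e) rep(NA_real_, 3L))
  names(se) <- c("log10_kon", "log10_koff", "log10_Rmax")
  model <- kineticsModel(10^p[1L], 10^p[2L], 10^p[3L])
  flags <- character(0)
  if (model@koff < 1e-5) flags <- c(flags, "koff_below_limit")
  list(model = model, KD = KD(model), se = se, rss = best$rss,
       converged = best$fit$info %in% 1:4, flags = flags)
}
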