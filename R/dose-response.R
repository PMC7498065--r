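# FRET dose-response analytics: 4-parameter logistic fitting and
# Cheng-Prusoff conversion of IC50 to Ki.

#' FretFit: a fitted 4-parameter logistic curve
#'
#' @slot bottom,top Lower/upper asymptotes (signal units; `top >= bottom`
#'   by canonical parameterisation).
#' @slot midpoint Curve midpoint, M: an apparent KD for saturation
#'   titrations or an IC50 for competition titrations.
#' @slot hill Hill slope (sign free: positive for rising curves, negative
#'   for inhibition).
#' @slot hillInRange Whether `|hill|` lies in the mass-action-plausible
#'   range [0.5, 2].
#' @slot Ki Inhibition constant, M (`NA` until attached via
#'   [chengPrusoff()]/[attachKi()]).
#' @slot rConc Labelled-partner concentration used for the Ki conversion,
#'   M.
#' @name FretFit-class
#' @aliases FretFit
#' @exportClass FretFit
setClass("FretFit",
  representation(
    bottom = "numeric", top = "numeric", midpoint = "numeric",
    hill = "numeric", hillInRange = "logical",
    Ki = "numeric", rConc = "numeric"
  )
)

setValidity("FretFit", function(object) {
  msg <- character()
  if (object@top < object@bottom) msg <- c(msg, "top must be >= bottom")
  if (object@midpoint <= 0) msg <- c(msg, "midpoint must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FretFit", function(object) {
  cat(sprintf(
    "FretFit: bottom %.3g, top %.3g, midpoint %.3g M, Hill %.3g%s\n",
    object@bottom, object@top, object@midpoint, object@hill,
    if (object@hillInRange) "" else " (outside [0.5, 2])"))
  if (!is.na(object@Ki))
    cat(sprintf("  Ki %.3g M (at [R] = %.3g M)\n", object@Ki, object@rConc))
})

#' @noRd
.fourPL <- function(x, bottom, top, midpoint, hill)
  bottom + (top - bottom) / (1 + (x / midpoint)^(-hill))

#' Fit a 4-parameter logistic dose-response curve
#'
#' Fits `y = bottom + (top - bottom) / (1 + (x / midpoint)^(-hill))` by
#' nonlinear least squares (midpoint in log10 space), trying both Hill
#' slope signs and keeping the better fit. One parameterisation covers
#' saturation (hill > 0) and inhibition (hill < 0) curves; the result is
#' canonicalised so `top >= bottom`. `hillInRange` records whether the
#' absolute Hill slope falls within [0.5, 2], the range expected for
#' reversible mass-action binding.
#'
#' @param x Concentrations (> 0), M.
#' @param y Signals.
#' @param backgroundWells Optional signal values from
#'   background/quenching wells: their mean is subtracted from `y` before
#'   fitting.
#' @return A [FretFit].
#' @examples
#' x <- 10^seq(-10, -6, length.out = 9)
#' y <- 100 / (1 + (x / 1e-8)^(-1))
#' fit4pl(x, y)
#' @export
fit4pl <- function(x, y, backgroundWells = NULL) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 5L) stop("need >= 5 points spanning the midpoint")
  if (any(x <= 0)) stop("concentrations must be > 0")
  if (length(unique(x)) == 1L) stop("degenerate x: all concentrations equal")
  if (!is.null(backgroundWells)) y <- y - mean(backgroundWells)

  resid <- function(p) {
    r <- y - .fourPL(x, p[1L], p[2L], 10^p[3L], p[4L])
    r[!is.finite(r)] <- 1e6
    r
  }
  midStart <- log10(exp(mean(log(range(x)))))
  starts <- list(c(min(y), max(y), midStart, 1),
                 c(min(y), max(y), midStart, -1))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("4PL fit failed from both Hill-slope signs")
  p <- best$fit$par
  bottom <- p[1L]; top <- p[2L]; mid <- 10^p[3L]; hill <- p[4L]
  if (top < bottom) {  # canonicalise via the 4PL symmetry
    tmp <- bottom; bottom <- top; top <- tmp; hill <- -hill
  }
  new("FretFit", bottom = bottom, top = top, midpoint = mid, hill = hill,
      hillInRange = abs(hill) >= 0.5 && abs(hill) <= 2,
      Ki = NA_real_, rConc = NA_real_)
}

#' Convert IC50 to Ki by the Cheng-Prusoff relation
#'
#' `Ki = IC50 / (1 + [R] / KDapp)`, where `[R]` is the concentration of
#' the labelled competing partner and `KDapp` its apparent dissociation
#' constant. Competition assays run with `[R]` fixed at `KDapp` therefore
#' give `Ki = IC50 / 2`; with `[R] = 0`, `Ki = IC50`.
#'
#' @param ic50 Half-maximal inhibitory concentration, M (> 0).
#' @param rConc Labelled-partner concentration, M (>= 0).
#' @param kdApp Apparent KD of the labelled partner, M (> 0).
#' @return Ki in M.
#' @examples
#' chengPrusoff(1e-8, 1e-9, 1e-9)  # 5e-9
#' @export
chengPrusoff <- function(ic50, rConc, kdApp) {
  if (ic50 <= 0) stop("ic50 must be > 0")
  if (rConc < 0) stop("rConc must be >= 0")
  if (kdApp <= 0) stop("kdApp must be > 0")
  ic50 / (1 + rConc / kdApp)
}

#' Attach a Cheng-Prusoff Ki to a competition FretFit
#'
#' @param fit A [FretFit] whose midpoint is an IC50.
#' @param rConc Labelled-partner concentration, M.
#' @param kdApp Apparent KD of the labelled partner, M.
#' @return The [FretFit] with `Ki` and `rConc` filled in.
#' @export
attachKi <- function(fit, rConc, kdApp) {
  fit@Ki <- chengPrusoff(fit@midpoint, rConc, kdApp)
  fit@rConc <- rConc
  fit
}
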