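# Enzyme-inhibition analysis: four-parameter-free dose-response fitting
# V = Vmax / (1 + (I/IC50)^h), Cheng-Prusoff Ki, mode-of-inhibition
# classification from the IC50-vs-substrate trend, and nanoDSF melt-curve
# Tm extraction from the 350/330 nm fluorescence ratio.

#' Fit an inhibitor dose-response curve
#'
#' Fits `V = Vmax / (1 + (I / IC50)^h)` by nonlinear least squares.
#' Positivity of IC50 and the slope h is enforced by fitting on
#' `log(IC50)` and `log(h)`; the IC50 start value comes from the data's
#' half-maximal crossing on the log10-concentration axis. Rows with
#' `I = 0` anchor Vmax (the model gives exactly Vmax there).
#'
#' @param inhibitor_uM inhibitor concentrations (uM, `>= 0`).
#' @param activity measured activities (same length).
#' @param start optional named list with any of `Vmax`, `IC50`, `h`.
#' @return object of class `dose_response_fit` with fields `Vmax`, `IC50`
#'   (uM), `h`, `residual_ss`, `converged`, `data`, and a `diagnostic`
#'   message when not converged. Methods: `print`, `coef`, `predict`,
#'   `fitted`, `residuals`.
#' @export
fit_dose_response <- function(inhibitor_uM, activity, start = NULL) {
  if (length(inhibitor_uM) != length(activity)) {
    stop("inhibitor and activity vectors differ in length")
  }
  if (any(inhibitor_uM < 0)) stop("inhibitor concentrations must be >= 0")
  if (any(!is.finite(activity))) stop("activities must be finite")
  dat <- data.frame(I = inhibitor_uM, V = activity)
  fail <- function(msg) {
    structure(list(Vmax = NA_real_, IC50 = NA_real_, h = NA_real_,
                   residual_ss = NA_real_, converged = FALSE,
                   diagnostic = msg, data = dat),
              class = "dose_response_fit")
  }
  if (length(unique(dat$I[dat$I > 0])) < 5) {
    return(fail("need at least 5 distinct positive inhibitor concentrations"))
  }
  v_top <- max(mean(dat$V[dat$I == min(dat$I)]), max(dat$V) * 0.5)
  v_span <- max(dat$V) - min(dat$V)
  if (v_span < 0.2 * max(abs(dat$V), 1e-12)) {
    return(fail("activity range too flat to define a transition"))
  }
  # half-maximal crossing on log10(I) for the IC50 start
  pos <- dat[dat$I > 0, ]
  agg <- stats::aggregate(V ~ I, pos, mean)
  agg <- agg[order(agg$I), ]
  half <- v_top / 2
  ic50_0 <- if (is.null(start$IC50)) {
    below <- which(agg$V <= half)
    if (length(below) == 0 || below[1] == 1) {
      stats::median(agg$I)
    } else {
      i <- below[1]
      l1 <- log10(agg$I[i - 1]); l2 <- log10(agg$I[i])
      v1 <- agg$V[i - 1]; v2 <- agg$V[i]
      10^(l1 + (half - v1) * (l2 - l1) / (v2 - v1))
    }
  } else start$IC50
  vmax_0 <- if (is.null(start$Vmax)) v_top else start$Vmax
  h_0 <- if (is.null(start$h)) 1 else start$h

  resid_fn <- function(p) {
    dat$V - p[1] / (1 + (dat$I / exp(p[2]))^exp(p[3]))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(vmax_0, log(ic50_0), log(h_0)),
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:3) {
    return(fail("nonlinear least squares did not converge"))
  }
  cf <- fit$par
  res <- structure(list(Vmax = cf[1],
                        IC50 = exp(cf[2]),
                        h = exp(cf[3]),
                        residual_ss = sum(fit$fvec^2),
                        converged = TRUE, diagnostic = NULL, data = dat),
                   class = "dose_response_fit")
  if (!is.finite(res$IC50) || res$Vmax <= 0) {
    return(fail("fit converged to implausible parameters"))
  }
  res
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Dose-response fit: Vmax = %.4g, IC50 = %.4g uM, h = %.3g (RSS %.3g)\n",
                x$Vmax, x$IC50, x$h, x$residual_ss))
  } else {
    cat("Dose-response fit: not converged (", x$diagnostic, ")\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(Vmax = object$Vmax, IC50 = object$IC50, h = object$h)
}

#' @param object a `dose_response_fit`.
#' @param newdata optional data.frame with column `I` (or a numeric vector
#'   of inhibitor concentrations).
#' @rdname fit_dose_response
#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  I <- if (is.null(newdata)) object$data$I
       else if (is.numeric(newdata)) newdata else newdata$I
  object$Vmax / (1 + (I / object$IC50)^object$h)
}

#' @export
fitted.dose_response_fit <- function(object, ...) predict(object)

#' @export
residuals.dose_response_fit <- function(object, ...) {
  object$data$V - fitted(object)
}

#' Cheng-Prusoff inhibition constant for a competitive inhibitor
#'
#' `Ki = IC50 / (1 + S / Km)`.
#'
#' @param ic50 fitted IC50 (uM), > 0.
#' @param S substrate concentration in the assay (uM, >= 0).
#' @param Km Michaelis constant of the enzyme for the substrate (uM), > 0.
#' @return Ki in uM.
#' @export
cheng_prusoff_ki <- function(ic50, S, Km) {
  if (any(ic50 <= 0)) stop("IC50 must be positive")
  if (any(Km <= 0)) stop("Km must be positive")
  if (any(S < 0)) stop("substrate concentration must be >= 0")
  ic50 / (1 + S / Km)
}

#' Predicted apparent IC50 versus substrate concentration
#'
#' Competitive inhibition: `IC50(S) = Ki * (1 + S/Km)`, strictly increasing
#' in S. Uncompetitive inhibition: `IC50(S) = Ki * (1 + Km/S)`, strictly
#' decreasing in S.
#'
#' @param Ki inhibition constant (uM), > 0.
#' @param Km Michaelis constant (uM), > 0.
#' @param mode `"competitive"` or `"uncompetitive"`.
#' @param S substrate concentrations (uM; must be > 0 for uncompetitive).
#' @return data.frame with columns `S` and `IC50`.
#' @export
predicted_ic50_curve <- function(Ki, Km, mode, S) {
  mode <- match.arg(mode, c("competitive", "uncompetitive"))
  stopifnot(Ki > 0, Km > 0)
  ic50 <- switch(mode,
    competitive = Ki * (1 + S / Km),
    uncompetitive = {
      if (any(S <= 0)) stop("uncompetitive IC50 needs S > 0")
      Ki * (1 + Km / S)
    })
  data.frame(S = S, IC50 = ic50)
}

#' Classify inhibition mode from the IC50-substrate trend
#'
#' A competitive inhibitor's apparent IC50 rises with substrate
#' concentration; an uncompetitive inhibitor's falls. The fold shift
#' `IC50(S_high) / IC50(S_low)` is compared against a relative dead band:
#' above `1 + rel_tol` is competitive, below `1 / (1 + rel_tol)`
#' uncompetitive, otherwise indeterminate. For a competitive call with a
#' supplied Km, Ki is the mean of the per-point Cheng-Prusoff values.
#'
#' @param S substrate concentrations (uM), at least 2 distinct levels.
#' @param ic50 fitted IC50s at those levels (uM).
#' @param rel_tol relative dead band; default 0.25 (typical inter-assay
#'   IC50 variability).
#' @param Km optional Michaelis constant (uM) for the Ki derivation.
#' @return list of class `inhibition_mode_call`: `mode`, `fold_shift`,
#'   `ic50_by_substrate` (data.frame), `Ki` (NA unless competitive with
#'   Km), `Km_used`.
#' @export
classify_inhibition_mode <- function(S, ic50, rel_tol = 0.25, Km = NULL) {
  if (length(S) != length(ic50)) stop("S and ic50 differ in length")
  if (length(S) < 2) stop("need IC50s at >= 2 substrate levels")
  if (anyDuplicated(S)) stop("duplicated substrate levels")
  if (any(ic50 <= 0)) stop("IC50 values must be positive")
  ord <- order(S)
  S <- S[ord]; ic50 <- ic50[ord]
  fold_shift <- ic50[length(ic50)] / ic50[1]
  mode <- if (fold_shift > 1 + rel_tol) "competitive"
          else if (fold_shift < 1 / (1 + rel_tol)) "uncompetitive"
          else "indeterminate"
  Ki <- NA_real_
  if (mode == "competitive" && !is.null(Km)) {
    Ki <- mean(cheng_prusoff_ki(ic50, S, Km))
  }
  structure(list(mode = mode, fold_shift = fold_shift,
                 ic50_by_substrate = data.frame(S = S, IC50 = ic50),
                 Ki = Ki, Km_used = if (is.null(Km)) NA_real_ else Km),
            class = "inhibition_mode_call")
}

#' @export
print.inhibition_mode_call <- function(x, ...) {
  cat("Inhibition mode:", x$mode,
      sprintf("(IC50 fold shift %.3g over S = %s uM)\n", x$fold_shift,
              paste(format(x$ic50_by_substrate$S), collapse = " -> ")))
  if (!is.na(x$Ki)) {
    cat(sprintf("  Cheng-Prusoff Ki = %.4g uM (Km = %.4g uM)\n", x$Ki, x$Km_used))
  }
  invisible(x)
}

#' Melting temperature from a nanoDSF unfolding curve
#'
#' The curve is the 350/330 nm fluorescence ratio versus temperature. The
#' `"derivative"` method (instrument convention) smooths the ratio with a
#' 5-point Savitzky-Golay filter, takes the first derivative and locates
#' its maximum with quadratic interpolation around the peak. The
#' `"boltzmann"` method fits a two-state sigmoid with linear pre- and
#' post-transition baselines and reports the midpoint.
#'
#' @param temperature_C temperatures (degrees C, strictly increasing,
#'   >= 10 points).
#' @param ratio 350/330 nm fluorescence ratios.
#' @param method `"derivative"` (default) or `"boltzmann"`.
#' @return Tm in degrees C.
#' @export
fit_melting_temperature <- function(temperature_C, ratio,
                                    method = c("derivative", "boltzmann")) {
  method <- match.arg(method)
  if (length(temperature_C) < 10) stop("melt curve needs >= 10 points")
  if (any(diff(temperature_C) <= 0)) {
    stop("temperatures must be strictly increasing")
  }
  if (length(ratio) != length(temperature_C)) {
    stop("temperature and ratio vectors differ in length")
  }
  rng <- diff(range(ratio))
  noise <- stats::mad(diff(ratio)) / sqrt(2)
  if (rng < max(10 * noise, 1e-9)) stop("no transition detected: curve is flat")

  if (method == "derivative") {
    sm <- signal::sgolayfilt(ratio, p = 2, n = 5)
    dT <- diff(temperature_C)
    dr <- diff(sm) / dT
    tmid <- (temperature_C[-1] + temperature_C[-length(temperature_C)]) / 2
    k <- which.max(dr)
    # a transition must stand out from the baseline slope and lie inside
    med <- stats::median(dr)
    if (k == 1 || k == length(dr) || (dr[k] - med) < 3 * stats::mad(dr)) {
      stop("no transition detected: derivative has no interior peak")
    }
    # localize the peak with a quadratic fit over its neighborhood (about
    # one transition half-width), which averages residual noise out of the
    # vertex position far better than a 3-point parabola
    win <- which(abs(tmid - tmid[k]) <= 2.5)
    if (length(win) < 3) win <- max(1, k - 1):min(length(dr), k + 1)
    x <- tmid[win]
    y <- dr[win]
    cf <- stats::coef(stats::lm(y ~ x + I(x^2)))
    tm <- if (is.na(cf[3]) || cf[3] >= 0) tmid[k] else -cf[2] / (2 * cf[3])
    if (tm < min(x) || tm > max(x)) tm <- tmid[k]
    return(unname(tm))
  }

  # boltzmann: two-state sigmoid with linear baselines
  T0 <- temperature_C
  dat <- data.frame(T = T0, r = ratio)
  tm0 <- T0[which.max(abs(stats::filter(ratio, c(-1, 0, 1), sides = 2)))]
  if (is.na(tm0)) tm0 <- stats::median(T0)
  lo0 <- stats::median(ratio[T0 <= stats::quantile(T0, 0.2)])
  hi0 <- stats::median(ratio[T0 >= stats::quantile(T0, 0.8)])
  sig_resid <- function(p) {
    low <- p[1] + p[2] * T0
    high <- p[3] + p[4] * T0
    dat$r - (low + (high - low) / (1 + exp((p[5] - T0) / p[6])))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(lo0, 0, hi0, 0, tm0, 1), fn = sig_resid,
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:3) {
    stop("no transition detected: sigmoid fit failed")
  }
  tm <- fit$par[5]
  if (tm < min(T0) || tm > max(T0)) {
    stop("no transition detected: fitted midpoint outside the scanned range")
  }
  tm
}

#' Thermal shift
#'
#' `delta_tm = Tm(holo) - Tm(apo)`; a positive value means the ligand
#' stabilizes the protein.
#'
#' @param tm_holo Tm with ligand (degrees C).
#' @param tm_apo Tm of the apo protein (degrees C).
#' @return signed shift in degrees C.
#' @export
delta_tm <- function(tm_holo, tm_apo) {
  stopifnot(is.finite(tm_holo), is.finite(tm_apo))
  tm_holo - tm_apo
}
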