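# The four binding/stability models: 1:1 interaction kinetics (SPR),
# Schild allosteric competition, hyperbolic IC50 inhibition and Boltzmann
# melting. All fitters use bounded Levenberg-Marquardt least squares
# (minpack.lm) and return a fit_result that is never silently
# non-converged.

fit_result <- function(model, estimate, se = NULL, residual_norm = NA_real_,
                       converged = FALSE, message = "", fit = NULL) {
  structure(list(model = model, estimate = estimate, se = se,
                 residual_norm = residual_norm, converged = converged,
                 message = message, fit = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$model,
      if (x$converged) "(converged)" else paste0("(NOT converged: ", x$message, ")"),
      "\n")
  est <- data.frame(estimate = unlist(x$estimate))
  if (!is.null(x$se)) est$se <- unlist(x$se)[rownames(est)]
  print(signif(est, 4))
  cat("residual norm:", signif(x$residual_norm, 4), "\n")
  invisible(x)
}

nls_safe <- function(formula, data, start, lower = NULL, upper = NULL) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500)
  args <- list(formula, data = data, start = start, control = ctrl)
  if (!is.null(lower)) args$lower <- lower
  if (!is.null(upper)) args$upper <- upper
  tryCatch(list(fit = do.call(minpack.lm::nlsLM, args), error = NULL),
           error = function(e) list(fit = NULL, error = conditionMessage(e)))
}

#' Equilibrium dissociation constant from rate constants
#'
#' \code{KD = koff / kon}, reported at 3 significant figures (the
#' convention of kinetic rate tables).
#'
#' @param kon Association rate constant (1/(M s)), > 0.
#' @param koff Dissociation rate constant (1/s), > 0.
#' @param digits Significant figures for reporting (default 3).
#' @return KD in M.
#' @export
#' @examples
#' kd_from_rates(1.86e5, 7.44e-3) # 4.00e-8
kd_from_rates <- function(kon, koff, digits = 3) {
  if (any(kon <= 0) || any(koff <= 0)) {
    stop("rate constants must be positive", call. = FALSE)
  }
  signif(koff / kon, digits)
}

#' Simulate a 1:1 interaction sensorgram
#'
#' Closed-form 1:1 (Langmuir) binding: during association
#' \code{R(t) = Rmax C/(C+KD) (1 - exp(-(kon C + koff) t))}; during
#' dissociation the response decays from its end-of-association value as
#' \code{exp(-koff t)}. The two phases are continuous at the boundary.
#'
#' @param kon,koff,Rmax Kinetic parameters (1/(M s), 1/s, response units).
#' @param conc Analyte concentration(s) in M; one sensorgram per value.
#' @param t_assoc,t_dissoc Phase durations in s (> 0).
#' @param dt Sampling interval in s.
#' @param noise_sd Gaussian noise SD in response units (0 = noiseless).
#' @param seed Seed used when \code{noise_sd > 0}.
#' @return Data frame: \code{time}, \code{response}, \code{concentration},
#'   \code{phase} ("association"/"dissociation").
#' @export
simulate_sensorgram <- function(kon, koff, Rmax, conc, t_assoc = 180,
                                t_dissoc = 300, dt = 1, noise_sd = 0,
                                seed = NULL) {
  stopifnot(kon > 0, koff > 0, Rmax > 0, all(conc >= 0))
  if (t_assoc <= 0 || t_dissoc <= 0) {
    stop("phase durations must be positive", call. = FALSE)
  }
  KD <- koff / kon
  one <- function(C) {
    ta <- seq(0, t_assoc, by = dt)
    td <- seq(dt, t_dissoc, by = dt)
    Req <- Rmax * C / (C + KD)
    Ra <- Req * (1 - exp(-(kon * C + koff) * ta))
    Rend <- Req * (1 - exp(-(kon * C + koff) * t_assoc))
    Rd <- Rend * exp(-koff * td)
    data.frame(time = c(ta, t_assoc + td), response = c(Ra, Rd),
               concentration = C,
               phase = rep(c("association", "dissociation"),
                           c(length(ta), length(td))))
  }
  out <- do.call(rbind, lapply(conc, one))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    out$response <- out$response + stats::rnorm(nrow(out), 0, noise_sd)
  }
  rownames(out) <- NULL
  out
}

sensorgram_model <- function(time, concentration, phase, lkon, lkoff, lRmax,
                             t_assoc) {
  kon <- exp(lkon); koff <- exp(lkoff); Rmax <- exp(lRmax)
  KD <- koff / kon
  Req <- Rmax * concentration / (concentration + KD)
  kobs <- kon * concentration + koff
  Rend <- Req * (1 - exp(-kobs * t_assoc))
  ifelse(phase == "association",
         Req * (1 - exp(-kobs * time)),
         Rend * exp(-koff * (time - t_assoc)))
}

#' Global 1:1 kinetic fit of sensorgrams
#'
#' Fits kon, koff and Rmax globally across all analyte concentrations by
#' bounded nonlinear least squares on log-scale parameters. Initial values:
#' koff from a log-linear fit of the dissociation phase, Rmax from the
#' largest plateau, kon from a small log-spaced grid search.
#'
#' @param data Sensorgram data frame (\code{time}, \code{response},
#'   \code{concentration}, \code{phase}) covering one or more
#'   concentrations, e.g. from \code{\link{simulate_sensorgram}}.
#' @param t_assoc End of the association phase in s; inferred from the data
#'   when omitted.
#' @return A \code{fit_result} with estimates \code{kon}, \code{koff},
#'   \code{KD}, \code{Rmax}.
#' @export
fit_1to1 <- function(data, t_assoc = NULL) {
  need <- c("time", "response", "concentration", "phase")
  stopifnot(all(need %in% names(data)))
  data <- data[data$concentration > 0, , drop = FALSE]
  if (is.null(t_assoc)) t_assoc <- max(data$time[data$phase == "association"])
  if (nrow(data) == 0 || stats::var(data$response) < .Machine$double.eps) {
    return(fit_result("1:1 kinetics", list(kon = NA, koff = NA, KD = NA,
                                           Rmax = NA),
                      converged = FALSE,
                      message = "degenerate input: no signal variation"))
  }
  dis <- data[data$phase == "dissociation" & data$response > 0, ]
  koff0 <- 1e-2
  if (nrow(dis) > 5) {
    sl <- tryCatch(-unname(stats::coef(stats::lm(
      log(response) ~ I(time - t_assoc), data = dis))[2]), error = function(e) NA)
    if (!is.na(sl) && sl > 0) koff0 <- sl
  }
  Rmax0 <- max(data$response) * 1.2
  sse_for <- function(lkon) {
    pred <- sensorgram_model(data$time, data$concentration, data$phase,
                             lkon, log(koff0), log(Rmax0), t_assoc)
    sum((data$response - pred)^2)
  }
  lkon_grid <- log(10^seq(2, 8, by = 0.5))
  lkon0 <- lkon_grid[which.min(vapply(lkon_grid, sse_for, numeric(1)))]
  res <- nls_safe(
    response ~ sensorgram_model(time, concentration, phase, lkon, lkoff,
                                lRmax, t_assoc),
    data = cbind(data, t_assoc = t_assoc),
    start = list(lkon = lkon0, lkoff = log(koff0), lRmax = log(Rmax0)))
  if (is.null(res$fit)) {
    return(fit_result("1:1 kinetics", list(kon = NA, koff = NA, KD = NA,
                                           Rmax = NA),
                      converged = FALSE, message = res$error))
  }
  cf <- stats::coef(res$fit)
  est <- list(kon = exp(cf[["lkon"]]), koff = exp(cf[["lkoff"]]),
              KD = exp(cf[["lkoff"]] - cf[["lkon"]]),
              Rmax = exp(cf[["lRmax"]]))
  vc <- tryCatch(stats::vcov(res$fit), error = function(e) NULL)
  se <- NULL
  if (!is.null(vc)) {
    se_l <- sqrt(diag(vc))
    kd_var <- vc["lkoff", "lkoff"] + vc["lkon", "lkon"] -
      2 * vc["lkon", "lkoff"]
    se <- list(kon = est$kon * se_l[["lkon"]],
               koff = est$koff * se_l[["lkoff"]],
               KD = est$KD * sqrt(max(kd_var, 0)),
               Rmax = est$Rmax * se_l[["lRmax"]])
  }
  fit_result("1:1 kinetics", est, se,
             residual_norm = sqrt(sum(stats::resid(res$fit)^2)),
             converged = res$fit$convInfo$isConv, fit = res$fit)
}

#' Schild affinity ratio
#'
#' Allosteric competition model for the apparent binder affinity in the
#' presence of a competitor at concentration x:
#' \code{KD'/KD = (x/B + 1) / (alpha x/B + 1)}, where B is the competitor's
#' own binding affinity and alpha the allosteric constant. The ratio is 1 at
#' x = 0 and saturates at 1/alpha.
#'
#' @param x Competitor concentration(s), M.
#' @param B Competitor affinity, M.
#' @param alpha Allosteric constant, 0 < alpha <= 1.
#' @return Affinity ratio(s) KD'/KD.
#' @export
#' @examples
#' schild_ratio(Inf, B = 1e-6, alpha = 0.017) # 1/0.017 = 58.8
schild_ratio <- function(x, B, alpha) {
  stopifnot(all(x >= 0), B > 0, alpha > 0, alpha <= 1)
  ifelse(is.infinite(x), 1 / alpha, (x / B + 1) / (alpha * x / B + 1))
}

#' Fit the Schild competition model
#'
#' Estimates the competitor affinity B and the allosteric constant alpha
#' from affinity ratios measured at several competitor concentrations.
#'
#' @param x Competitor concentrations, M (>= 3 distinct values including 0
#'   recommended).
#' @param ratio Measured KD'/KD values.
#' @return A \code{fit_result} with estimates \code{B}, \code{alpha} and the
#'   derived \code{saturating_ratio} = 1/alpha.
#' @export
fit_schild <- function(x, ratio) {
  stopifnot(length(x) == length(ratio), all(x >= 0), all(ratio > 0))
  if (stats::var(ratio) < .Machine$double.eps) {
    # flat at 1: no competition, alpha -> 1
    est <- list(B = NA_real_, alpha = 1, saturating_ratio = 1)
    return(fit_result("Schild", est, converged = all(abs(ratio - 1) < 1e-6),
                      message = "flat ratios",
                      residual_norm = sqrt(sum((ratio - mean(ratio))^2))))
  }
  alpha0 <- min(1, 1 / max(ratio))
  half <- (1 + 1 / alpha0) / 2
  B0 <- if (any(ratio >= half & x > 0)) min(x[ratio >= half & x > 0])
        else stats::median(x[x > 0])
  res <- nls_safe(ratio ~ (x / B + 1) / (alpha * x / B + 1),
                  data = data.frame(x = x, ratio = ratio),
                  start = list(B = B0, alpha = alpha0),
                  lower = c(B = 1e-15, alpha = 1e-8),
                  upper = c(B = Inf, alpha = 1))
  if (is.null(res$fit)) {
    return(fit_result("Schild", list(B = NA, alpha = NA), converged = FALSE,
                      message = res$error))
  }
  cf <- stats::coef(res$fit)
  se_raw <- tryCatch(sqrt(diag(stats::vcov(res$fit))), error = function(e) NULL)
  se <- if (!is.null(se_raw)) list(B = se_raw[["B"]], alpha = se_raw[["alpha"]])
  fit_result("Schild",
             list(B = cf[["B"]], alpha = cf[["alpha"]],
                  saturating_ratio = 1 / cf[["alpha"]]),
             se, residual_norm = sqrt(sum(stats::resid(res$fit)^2)),
             converged = res$fit$convInfo$isConv, fit = res$fit)
}

#' Hyperbolic inhibition curve
#'
#' Residual activity at inhibitor concentration x:
#' \code{y = y0 + a IC50/(IC50 + x)} with \code{y(0) = y0 + a} (uninhibited,
#' normalized to 100\%), \code{y(Inf) = y0} (residual activity) and
#' \code{y(IC50) = y0 + a/2}.
#'
#' @param x Inhibitor concentration(s), M.
#' @param y0 Residual activity (\%).
#' @param a Inhibitable span (\%).
#' @param ic50 Half-maximal inhibitory concentration, M.
#' @return Activity (\%).
#' @export
inhibition_curve <- function(x, y0, a, ic50) {
  stopifnot(all(x >= 0), ic50 > 0)
  y0 + a * ic50 / (ic50 + x)
}

#' Fit the hyperbolic inhibition model
#'
#' @param x Inhibitor concentrations, M.
#' @param y Activities (\%, uninhibited near 100).
#' @return A \code{fit_result} with estimates \code{y0}, \code{a},
#'   \code{IC50}.
#' @export
fit_inhibition <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0))
  if (stats::var(y) < .Machine$double.eps) {
    return(fit_result("IC50 inhibition", list(y0 = NA, a = NA, IC50 = NA),
                      converged = FALSE, message = "flat dose-response"))
  }
  y0_0 <- min(y); a0 <- max(y) - min(y)
  half <- y0_0 + a0 / 2
  below <- which(y <= half & x > 0)
  ic0 <- if (length(below) > 0) min(x[below]) else stats::median(x[x > 0])
  res <- nls_safe(y ~ y0 + a * ic50 / (ic50 + x),
                  data = data.frame(x = x, y = y),
                  start = list(y0 = y0_0, a = a0, ic50 = ic0),
                  lower = c(y0 = 0, a = 0, ic50 = 1e-15))
  if (is.null(res$fit)) {
    return(fit_result("IC50 inhibition", list(y0 = NA, a = NA, IC50 = NA),
                      converged = FALSE, message = res$error))
  }
  cf <- stats::coef(res$fit)
  se_raw <- tryCatch(sqrt(diag(stats::vcov(res$fit))), error = function(e) NULL)
  se <- if (!is.null(se_raw)) list(y0 = se_raw[["y0"]], a = se_raw[["a"]],
                                   IC50 = se_raw[["ic50"]])
  fit_result("IC50 inhibition",
             list(y0 = cf[["y0"]], a = cf[["a"]], IC50 = cf[["ic50"]]),
             se, residual_norm = sqrt(sum(stats::resid(res$fit)^2)),
             converged = res$fit$convInfo$isConv, fit = res$fit)
}

#' Boltzmann sigmoid melting curve
#'
#' \code{signal(T) = bottom + (top - bottom) / (1 + exp((Tm - T)/slope))}.
#' At T = Tm the curve passes through (bottom + top)/2. A negative slope
#' describes a signal that is lost upon melting (the usual direction for
#' ligand-binding readouts).
#'
#' @param temperature Temperatures, degC.
#' @param bottom,top Lower/upper asymptotes (signal units, bottom < top).
#' @param Tm Apparent melting temperature, degC.
#' @param slope Transition width parameter, degC (sign sets direction).
#' @return Signal values.
#' @export
boltzmann_curve <- function(temperature, bottom, top, Tm, slope) {
  stopifnot(bottom < top, slope != 0)
  bottom + (top - bottom) / (1 + exp((Tm - temperature) / slope))
}

#' Fit a Boltzmann melting curve
#'
#' Estimates the apparent melting temperature Tm (sigmoid inflection) from a
#' melt curve. Initialization: asymptotes from the data range, Tm from the
#' temperature of steepest signal change, slope sign from the direction of
#' that change.
#'
#' @param temperature Temperatures, degC (>= 6 points spanning the
#'   transition recommended).
#' @param signal Measured signal.
#' @return A \code{fit_result} with estimates \code{Tm}, \code{slope},
#'   \code{bottom}, \code{top}.
#' @export
fit_melt <- function(temperature, signal) {
  stopifnot(length(temperature) == length(signal))
  o <- order(temperature)
  temperature <- temperature[o]; signal <- signal[o]
  if (stats::var(signal) < .Machine$double.eps ||
      diff(range(signal)) < 1e-3 * max(abs(signal), 1)) {
    return(fit_result("Boltzmann melt", list(Tm = NA, slope = NA,
                                             bottom = NA, top = NA),
                      converged = FALSE, message = "flat melt curve"))
  }
  # initialize on per-temperature replicate means so repeated temperatures
  # cannot produce zero-width finite differences
  tm_u <- sort(unique(temperature))
  s_u <- vapply(tm_u, function(tt) mean(signal[temperature == tt]), numeric(1))
  d <- diff(s_u) / diff(tm_u)
  imax <- which.max(abs(d))
  Tm0 <- mean(tm_u[imax + 0:1])
  slope0 <- (diff(range(temperature)) / 10) * sign(d[imax])
  res <- nls_safe(signal ~ bottom + (top - bottom) /
                    (1 + exp((Tm - temperature) / slope)),
                  data = data.frame(temperature = temperature, signal = signal),
                  start = list(bottom = min(signal), top = max(signal),
                               Tm = Tm0, slope = slope0))
  if (is.null(res$fit)) {
    return(fit_result("Boltzmann melt", list(Tm = NA, slope = NA,
                                             bottom = NA, top = NA),
                      converged = FALSE, message = res$error))
  }
  cf <- stats::coef(res$fit)
  tm_in_range <- cf[["Tm"]] >= min(temperature) && cf[["Tm"]] <= max(temperature)
  se_raw <- tryCatch(sqrt(diag(stats::vcov(res$fit))), error = function(e) NULL)
  se <- if (!is.null(se_raw)) as.list(se_raw)
  fit_result("Boltzmann melt",
             list(Tm = cf[["Tm"]], slope = cf[["slope"]],
                  bottom = cf[["bottom"]], top = cf[["top"]]),
             se, residual_norm = sqrt(sum(stats::resid(res$fit)^2)),
             converged = res$fit$convInfo$isConv && tm_in_range,
             message = if (!tm_in_range) "Tm outside measured range" else "",
             fit = res$fit)
}

#' Melting-temperature shift
#'
#' \code{delta_tm = Tm(with binder) - Tm(without binder)}; a positive shift
#' indicates thermal stabilization by the binder.
#'
#' @param with_fit,without_fit \code{fit_result}s from \code{\link{fit_melt}}
#'   (or numeric Tm values).
#' @return Temperature shift in degC.
#' @export
delta_tm <- function(with_fit, without_fit) {
  tm <- function(x) {
    if (inherits(x, "fit_result")) {
      if (!x$converged) stop("melt fit did not converge", call. = FALSE)
      x$estimate$Tm
    } else as.numeric(x)
  }
  tm(with_fit) - tm(without_fit)
}
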