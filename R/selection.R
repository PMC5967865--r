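# Selection analytics: absolute qPCR quantification against standard
# curves, enrichment folds, expected-unique diversity arithmetic, the
# selection-cascade bottleneck model and ELISA hit calling.

#' qPCR standard curve
#'
#' A standard curve Ct = intercept + slope * log10(copies). The
#' amplification efficiency derives from the slope as
#' \code{10^(-1/slope) - 1} (slope -3.32 corresponds to 100\%).
#'
#' @param slope Cycles per log10(copies) (negative).
#' @param intercept Ct at 1 copy.
#' @param ct_range Optional calibrated Ct range \code{c(min, max)}; values
#'   outside it are flagged by \code{\link{quantify}}.
#' @param efficiency_band Accepted efficiency band (default 0.90-1.10);
#'   curves outside it trigger a warning.
#' @return A \code{standard_curve} object.
#' @export
#' @examples
#' sc <- standard_curve(slope = -3.3219, intercept = 38)
#' sc$efficiency # ~1 (100%)
standard_curve <- function(slope, intercept, ct_range = NULL,
                           efficiency_band = c(0.90, 1.10)) {
  stopifnot(slope < 0)
  eff <- 10^(-1 / slope) - 1
  if (eff < efficiency_band[1] || eff > efficiency_band[2]) {
    warning(sprintf("PCR efficiency %.3f outside accepted band [%.2f, %.2f]",
                    eff, efficiency_band[1], efficiency_band[2]))
  }
  structure(list(slope = slope, intercept = intercept, efficiency = eff,
                 ct_range = ct_range),
            class = "standard_curve")
}

#' Fit a standard curve from a dilution series
#' @param ct Observed Ct values.
#' @param copies Known input copy numbers.
#' @param ... Passed to \code{\link{standard_curve}}.
#' @return A \code{standard_curve} with the calibrated Ct range attached.
#' @export
fit_standard_curve <- function(ct, copies, ...) {
  fit <- stats::lm(ct ~ log10(copies))
  standard_curve(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 ct_range = range(ct), ...)
}

#' Absolute quantification of qPCR measurements
#'
#' Converts Ct values to copy numbers through a standard curve:
#' \code{copies = 10^((intercept - Ct) / (-slope))}. Technical replicates of
#' a sample are aggregated on the Ct scale by default (mean Ct, then
#' transform); the replicate SD is propagated to the copy scale by the delta
#' method.
#'
#' @param measurements Data frame with columns \code{sample_id}, \code{Ct}
#'   and optionally \code{replicate} and \code{primer_pair}.
#' @param sc A \code{\link{standard_curve}}.
#' @param aggregate \code{"ct"} (default) or \code{"copies"} (mean of
#'   back-transformed copies).
#' @return Data frame with one row per sample: \code{copies},
#'   \code{copies_sd}, \code{n}, and \code{out_of_range} flag for Ct values
#'   outside the calibrated range.
#' @export
quantify <- function(measurements, sc, aggregate = c("ct", "copies")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(sc, "standard_curve"),
            all(c("sample_id", "Ct") %in% names(measurements)))
  if (any(measurements$Ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  to_copies <- function(ct) 10^((sc$intercept - ct) / (-sc$slope))
  out <- do.call(rbind, lapply(split(measurements, measurements$sample_id),
    function(g) {
      flag <- !is.null(sc$ct_range) &&
        any(g$Ct < sc$ct_range[1] | g$Ct > sc$ct_range[2])
      if (aggregate == "ct") {
        m_ct <- mean(g$Ct)
        sd_ct <- stats::sd(g$Ct)
        copies <- to_copies(m_ct)
        # d copies / d Ct = -copies * ln(10) / (-slope)
        copies_sd <- if (is.na(sd_ct)) NA_real_ else
          abs(copies * log(10) / sc$slope) * sd_ct
      } else {
        cps <- to_copies(g$Ct)
        copies <- mean(cps)
        copies_sd <- stats::sd(cps)
      }
      data.frame(sample_id = g$sample_id[1], copies = copies,
                 copies_sd = copies_sd, n = nrow(g), out_of_range = flag,
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Fold enrichment of target over background
#'
#' The enrichment of a selection round is the fold excess of polynucleotide
#' copies eluted against the target versus an analogous round against a
#' background protein. SDs, when given, are propagated to the ratio
#' (independent relative errors in quadrature).
#'
#' @param target_copies,background_copies Copy numbers (means over
#'   replicates).
#' @param target_sd,background_sd Optional SDs.
#' @param background_floor Detection floor; a background at or below zero is
#'   replaced by the floor and the result flagged as a lower bound.
#' @return List with \code{fold}, \code{fold_sd}, \code{lower_bound} flag.
#' @export
#' @examples
#' enrichment_fold(1.7e5, 1.0e3)$fold # 170
enrichment_fold <- function(target_copies, background_copies,
                            target_sd = NA_real_, background_sd = NA_real_,
                            background_floor = 1) {
  lower_bound <- FALSE
  if (background_copies <= 0) {
    background_copies <- background_floor
    lower_bound <- TRUE
  }
  fold <- target_copies / background_copies
  fold_sd <- if (is.na(target_sd) && is.na(background_sd)) NA_real_ else {
    rt <- if (is.na(target_sd)) 0 else target_sd / target_copies
    rb <- if (is.na(background_sd)) 0 else background_sd / background_copies
    fold * sqrt(rt^2 + rb^2)
  }
  list(fold = fold, fold_sd = fold_sd, lower_bound = lower_bound)
}

#' Expected number of distinct members among n draws
#'
#' Under uniform sampling with replacement from a pool of diversity D, the
#' expected number of distinct members observed in n draws is
#' \code{D * (1 - (1 - 1/D)^n)}. Monotone increasing in n and bounded by
#' \code{min(n, D)}.
#'
#' @param n Number of draws (>= 0).
#' @param D Pool diversity (>= 1).
#' @return Expected distinct count.
#' @export
#' @examples
#' expected_unique(48, 100)
expected_unique <- function(n, D) {
  stopifnot(all(n >= 0), all(D >= 1))
  # expm1/log1p keep precision when D >> n
  out <- suppressWarnings(-D * expm1(n * log1p(-1 / D)))
  ifelse(D == 1, as.numeric(n > 0), out)
}

#' Estimate pool diversity from an observed unique fraction
#'
#' Inverts \code{\link{expected_unique}}: given \code{u} unique members among
#' \code{n} sampled (e.g. 40 unique of 48 sequenced hits), solves for the
#' pool diversity \code{D} with \code{expected_unique(n, D) = u}.
#'
#' @param unique_observed Distinct members observed (\code{1 <= u <= n}).
#' @param n Total draws.
#' @param D_max Upper search bound.
#' @return Estimated diversity (\code{Inf} when all draws were unique).
#' @export
#' @examples
#' estimate_diversity(40, 48)
estimate_diversity <- function(unique_observed, n, D_max = 1e15) {
  stopifnot(unique_observed >= 1, unique_observed <= n)
  if (unique_observed == n) return(Inf)
  f <- function(logD) expected_unique(n, exp(logD)) - unique_observed
  exp(stats::uniroot(f, c(log(1 + 1e-9), log(D_max)), tol = 1e-12)$root)
}

#' Expected diversity through the selection cascade
#'
#' Expectation-level propagation of binder diversity through the
#' ribosome-display / phage-display selection cascade. Each step draws a
#' number of molecules from the surviving pool and the expected distinct
#' count follows \code{\link{expected_unique}}. Steps: display (molecules
#' displayed on ribosomes), round-1 capture and recovery (molecules eluted
#' and successfully amplified), phage library construction (transformants),
#' and phage infection (eluted phages times the infection rate).
#'
#' @param pool_diversity Diversity of the input pool (default the
#'   experimental library diversity, 9e12).
#' @param displayed Molecules displayed in the initial round (default 1e12).
#' @param round1_output Molecules recovered from the initial display round
#'   (default 2e6, within the observed 1e6-5e6 band).
#' @param phage_library_size Transformants in the focused phage library
#'   (default 1e7).
#' @param eluted_phages Phages eluted after the first phage round (default
#'   1e8).
#' @param infection_rate Fraction of eluted phages that infect (default
#'   0.02; observed 2-5\%).
#' @return List with \code{steps} (data.frame: step, sampled, diversity) and
#'   \code{bottleneck} (step with the largest log10 diversity loss).
#' @export
cascade_diversity <- function(pool_diversity = 9e12, displayed = 1e12,
                              round1_output = 2e6, phage_library_size = 1e7,
                              eluted_phages = 1e8, infection_rate = 0.02) {
  stopifnot(infection_rate > 0, infection_rate <= 1)
  steps <- list(
    display = displayed,
    round1_recovery = round1_output,
    phage_library = phage_library_size,
    infection = eluted_phages * infection_rate
  )
  D <- pool_diversity
  rows <- list()
  for (nm in names(steps)) {
    D_new <- expected_unique(steps[[nm]], D)
    rows[[nm]] <- data.frame(step = nm, sampled = steps[[nm]],
                             diversity = D_new, stringsAsFactors = FALSE)
    D <- D_new
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  loss <- log10(c(pool_diversity, df$diversity[-nrow(df)])) - log10(df$diversity)
  list(steps = df, bottleneck = df$step[which.max(loss)])
}

#' ELISA hit calling
#'
#' Calls a well a hit when its signal-to-background absorbance ratio is at
#' least \code{threshold_ratio}. Backgrounds below \code{background_floor}
#' are replaced by the floor and flagged.
#'
#' @param signal,background Absorbances (>= 0), vectorized.
#' @param threshold_ratio Hit threshold (default 3).
#' @param background_floor Floor for near-zero backgrounds (default 0.01).
#' @return Data frame with \code{signal}, \code{background}, \code{ratio},
#'   \code{hit}, \code{flagged}; the fraction of positive wells is attached
#'   as attribute \code{"fraction_positive"}.
#' @export
elisa_call <- function(signal, background, threshold_ratio = 3,
                       background_floor = 0.01) {
  stopifnot(all(signal >= 0), all(background >= 0), threshold_ratio > 0)
  flagged <- background < background_floor
  bg <- pmax(background, background_floor)
  ratio <- signal / bg
  out <- data.frame(signal = signal, background = background, ratio = ratio,
                    hit = ratio >= threshold_ratio, flagged = flagged)
  attr(out, "fraction_positive") <- mean(out$hit)
  out
}
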