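# Synthetic-data generation: every dataset the analysis functions consume
# can be produced here with declared true parameters, noise models and
# seeds, and comes with a truth record for parameter-recovery testing.
#
# Default regimes mirror the platform's assays: analyte concentrations
# 0/1/3/9/27/81 nM, maltose series 0-100 uM, temperature gradients across
# twelve wells, qPCR efficiencies in the 95-98% band. Default noise: SPR 1%
# of Rmax, melt 2% of the signal span, qPCR Ct SD 0.15 cycles.

.scenario_defaults <- list(
  spr = list(kon = 1.86e5, koff = 7.44e-3, Rmax = 100,
             conc = c(0, 1, 3, 9, 27, 81) * 1e-9,
             t_assoc = 180, t_dissoc = 300, dt = 2, noise_frac = 0.01),
  schild = list(B = 1.0e-6, alpha = 0.017,
                x = c(0, 5, 10, 25, 50, 100) * 1e-6, noise_cv = 0.05),
  inhibition = list(y0 = 20, a = 80, ic50 = 62e-9,
                    x = c(0, 3^(0:7)) * 1e-9, noise_sd = 2, replicates = 3),
  melt = list(bottom = 0.1, top = 1.0, Tm = 45, slope = -1.5,
              temperature = seq(30, 60, length.out = 12),
              noise_frac = 0.02, replicates = 3),
  qpcr_dilution = list(efficiency = 0.96, intercept = 38,
                       copies = 10^(3:8), ct_sd = 0.15, replicates = 3),
  qpcr_selection = list(efficiency = 0.96, intercept = 38,
                        target_copies = 1.7e5, background_copies = 1e3,
                        ct_sd = 0.15, replicates = 3),
  elisa_plate = list(n_wells = 96, hit_fraction = 0.6, background_mean = 0.08,
                     hit_ratio = 5, noise_cv = 0.1),
  library_fasta = list(library = "concave", n = 10)
)

#' Scenario configuration for synthetic datasets
#'
#' @param scenario Scenario name; one of
#'   \code{names(sybodykit:::.scenario_defaults)}: \code{spr},
#'   \code{schild}, \code{inhibition}, \code{melt}, \code{qpcr_dilution},
#'   \code{qpcr_selection}, \code{elisa_plate}, \code{library_fasta}.
#' @param seed Integer seed; regeneration from the same config is
#'   bit-identical.
#' @param ... Overrides of the scenario's default parameters.
#' @return A \code{scenario_config} list with \code{scenario}, \code{seed},
#'   \code{params}.
#' @export
scenario_config <- function(scenario, seed = 1, ...) {
  if (!scenario %in% names(.scenario_defaults)) {
    stop("unknown scenario: '", scenario, "' (expected one of ",
         paste(names(.scenario_defaults), collapse = ", "), ")",
         call. = FALSE)
  }
  params <- utils::modifyList(.scenario_defaults[[scenario]], list(...))
  structure(list(scenario = scenario, seed = as.integer(seed),
                 params = params),
            class = "scenario_config")
}

#' Generate a synthetic dataset with its truth record
#'
#' Produces the dataset of the requested scenario together with a truth
#' record of the generating parameters. Deterministic per seed.
#'
#' @param config A \code{\link{scenario_config}} (or a scenario name, in
#'   which case \code{seed} and \code{...} build the config).
#' @param seed,... Used when \code{config} is a scenario name.
#' @return List with \code{data} (a data.frame, or sequence sets for
#'   \code{library_fasta}), \code{truth} (named list of generating
#'   parameters) and \code{config}.
#' @export
#' @examples
#' d <- sy_generate("melt", seed = 7)
#' fit_melt(d$data$temperature, d$data$signal)$estimate$Tm # ~ d$truth$Tm
sy_generate <- function(config, seed = 1, ...) {
  if (is.character(config)) config <- scenario_config(config, seed = seed, ...)
  stopifnot(inherits(config, "scenario_config"))
  p <- config$params
  set.seed(config$seed)
  gen <- switch(config$scenario,
    spr = {
      data <- simulate_sensorgram(p$kon, p$koff, p$Rmax, p$conc,
                                  t_assoc = p$t_assoc, t_dissoc = p$t_dissoc,
                                  dt = p$dt,
                                  noise_sd = p$noise_frac * p$Rmax)
      list(data = data,
           truth = list(kon = p$kon, koff = p$koff, KD = p$koff / p$kon,
                        Rmax = p$Rmax))
    },
    schild = {
      r <- schild_ratio(p$x, p$B, p$alpha)
      r_obs <- r * (1 + stats::rnorm(length(r), 0, p$noise_cv))
      list(data = data.frame(x = p$x, ratio = pmax(r_obs, 1e-6)),
           truth = list(B = p$B, alpha = p$alpha,
                        saturating_ratio = 1 / p$alpha))
    },
    inhibition = {
      x <- rep(p$x, each = p$replicates)
      y <- inhibition_curve(x, p$y0, p$a, p$ic50) +
        stats::rnorm(length(x), 0, p$noise_sd)
      list(data = data.frame(x = x, y = y,
                             replicate = rep(seq_len(p$replicates),
                                             times = length(p$x))),
           truth = list(y0 = p$y0, a = p$a, IC50 = p$ic50))
    },
    melt = {
      temp <- rep(p$temperature, each = p$replicates)
      s <- boltzmann_curve(temp, p$bottom, p$top, p$Tm, p$slope) +
        stats::rnorm(length(temp), 0, p$noise_frac * (p$top - p$bottom))
      list(data = data.frame(temperature = temp, signal = s,
                             replicate = rep(seq_len(p$replicates),
                                             times = length(p$temperature))),
           truth = list(bottom = p$bottom, top = p$top, Tm = p$Tm,
                        slope = p$slope))
    },
    qpcr_dilution = {
      slope <- -1 / log10(1 + p$efficiency)
      rows <- expand.grid(copies = p$copies,
                          replicate = seq_len(p$replicates))
      ct <- p$intercept + slope * log10(rows$copies) +
        stats::rnorm(nrow(rows), 0, p$ct_sd)
      list(data = data.frame(sample_id = sprintf("dil_%g", rows$copies),
                             Ct = ct, replicate = rows$replicate,
                             true_copies = rows$copies),
           truth = list(slope = slope, intercept = p$intercept,
                        efficiency = p$efficiency, copies = p$copies))
    },
    qpcr_selection = {
      slope <- -1 / log10(1 + p$efficiency)
      rows <- expand.grid(sample_id = c("target", "background"),
                          replicate = seq_len(p$replicates),
                          stringsAsFactors = FALSE)
      true_c <- ifelse(rows$sample_id == "target", p$target_copies,
                       p$background_copies)
      ct <- p$intercept + slope * log10(true_c) +
        stats::rnorm(nrow(rows), 0, p$ct_sd)
      list(data = data.frame(sample_id = rows$sample_id, Ct = ct,
                             replicate = rows$replicate),
           truth = list(slope = slope, intercept = p$intercept,
                        fold = p$target_copies / p$background_copies))
    },
    elisa_plate = {
      is_hit <- stats::runif(p$n_wells) < p$hit_fraction
      bg <- p$background_mean * (1 + stats::rnorm(p$n_wells, 0, p$noise_cv))
      sig <- bg * ifelse(is_hit, p$hit_ratio, 1) *
        (1 + stats::rnorm(p$n_wells, 0, p$noise_cv))
      list(data = data.frame(well = seq_len(p$n_wells),
                             row = rep(LETTERS[1:8], length.out = p$n_wells),
                             col = rep(1:12, each = 8)[seq_len(p$n_wells)],
                             signal = pmax(sig, 0), background = pmax(bg, 0),
                             true_hit = is_hit),
           truth = list(hit_fraction = p$hit_fraction,
                        hit_ratio = p$hit_ratio))
    },
    library_fasta = {
      sch <- randomization_scheme(p$library)
      lib <- sample_library(sch, p$n, seed = config$seed)
      list(data = lib,
           truth = list(library = p$library, n = p$n,
                        n_randomized = n_randomized(sch)))
    })
  c(gen, list(config = config))
}
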