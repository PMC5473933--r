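#' Sensor-channel response model
#'
#' Describes one coated channel of a nanomechanical sensor array as a set of
#' independent first-order sorption units, one per headspace component. The
#' channel's output is the sum of the component signals: during vapour
#' injection each component relaxes towards its equilibrium level
#' `sensitivity * concentration` with time constant `tau_ads`; during purge it
#' decays with `tau_des`. Gaussian noise, a linear baseline drift and a
#' multiplicative instability of the first two cycles complete the model.
#'
#' @param name Channel name (the coating identity).
#' @param sensitivity Named numeric vector: equilibrium signal (mV) per
#'   concentration unit, one entry per component.
#' @param tau_ads,tau_des Named numeric vectors of adsorption and desorption
#'   time constants (s), same components as `sensitivity`; all must be > 0.
#' @param noise_sd Standard deviation of additive Gaussian noise (mV).
#' @param drift_rate Linear baseline drift (mV/s).
#' @param instability_factor Multiplicative factor applied to the response
#'   during the first two cycles, mimicking the initial instability of fresh
#'   measurements; 1 means no instability.
#' @param archetype Optional `"hydrophobic"` or `"hydrophilic"`; when given,
#'   the ethanol-to-water sensitivity ratio is checked for consistency
#'   (hydrophobic > 1, hydrophilic < 1).
#' @return An object of class `channel_model`.
#' @export
channel_model <- function(name, sensitivity, tau_ads, tau_des,
                          noise_sd = 0.5, drift_rate = 0.003,
                          instability_factor = 0.9, archetype = NULL) {
  comp <- names(sensitivity)
  if (is.null(comp)) stop("sensitivity must be a named vector over components")
  if (!identical(comp, names(tau_ads)) || !identical(comp, names(tau_des)))
    stop("sensitivity, tau_ads and tau_des must share component names")
  if (any(tau_ads <= 0) || any(tau_des <= 0))
    stop("all time constants must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(archetype)) {
    archetype <- match.arg(archetype, c("hydrophobic", "hydrophilic"))
    if (all(c("ethanol", "water") %in% comp)) {
      ratio <- sensitivity[["ethanol"]] / sensitivity[["water"]]
      if (archetype == "hydrophobic" && ratio <= 1)
        stop("hydrophobic archetype requires ethanol-to-water sensitivity ratio > 1")
      if (archetype == "hydrophilic" && ratio >= 1)
        stop("hydrophilic archetype requires ethanol-to-water sensitivity ratio < 1")
    }
  }
  structure(list(name = name, sensitivity = sensitivity, tau_ads = tau_ads,
                 tau_des = tau_des, noise_sd = noise_sd,
                 drift_rate = drift_rate,
                 instability_factor = instability_factor,
                 archetype = archetype),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat("Channel", shQuote(x$name),
      if (!is.null(x$archetype)) paste0("(", x$archetype, ")"), "\n")
  cat("  components:", paste(names(x$sensitivity), collapse = ", "), "\n")
  cat("  noise_sd:", x$noise_sd, "mV; drift:", x$drift_rate,
      "mV/s; instability:", x$instability_factor, "\n")
  invisible(x)
}

#' Default four-channel array of nanoparticle-coated archetypes
#'
#' Two hydrophobic coatings (octadecyl- and phenyl-functionalised
#' nanoparticle archetypes, high ethanol affinity) and two hydrophilic ones
#' (aminopropyl and vinyl archetypes, water-dominated response). Ethanol and
#' water sorb quickly; flavour components sorb and desorb slowly, so the
#' quasi-equilibrium slope of a cycle carries flavour rather than alcohol
#' information, while the rise slope, decay slope and peak height track the
#' ethanol level on hydrophobic coatings.
#'
#' @param n_flavors Number of flavour components (matching
#'   [sample_components()]).
#' @return A list of four [channel_model()] objects.
#' @export
default_channels <- function(n_flavors = 6) {
  comp_names <- c("ethanol", "water", paste0("flavor", seq_len(n_flavors)))
  rep_f <- function(x) rep_len(x, n_flavors)
  mk <- function(name, s_eth, s_wat, s_flav, archetype, noise_sd, drift) {
    s <- c(s_eth, s_wat, rep_f(s_flav))
    names(s) <- comp_names
    ta <- c(0.2, 0.3, rep_f(c(12, 15, 18, 10, 14, 20)))
    td <- c(0.6, 0.5, rep_f(c(20, 25, 30, 18, 22, 35)))
    names(ta) <- names(td) <- comp_names
    channel_model(name, s, ta, td, noise_sd = noise_sd, drift_rate = drift,
                  instability_factor = 0.9, archetype = archetype)
  }
  list(
    mk("c18_np",         1.00, 0.08, c(0.35, 0.15, 0.30, 0.20, 0.10, 0.25),
       "hydrophobic", 0.90, 0.003),
    mk("phenyl_np",      0.85, 0.10, c(0.20, 0.30, 0.15, 0.25, 0.30, 0.10),
       "hydrophobic", 0.81, 0.002),
    mk("aminopropyl_np", 0.10, 0.90, c(0.40, 0.25, 0.35, 0.30, 0.20, 0.35),
       "hydrophilic", 0.90, 0.004),
    mk("vinyl_np",       0.15, 0.70, c(0.30, 0.35, 0.20, 0.40, 0.25, 0.30),
       "hydrophilic", 0.99, 0.003)
  )
}
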