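#' Default liquid-sample table for alcohol-content quantification
#'
#' Returns the standard panel of 35 liquid samples used for alcohol-content
#' estimation: 26 named liquids (commercial liquors, non-alcoholic drinks and
#' waters) plus 9 water/ethanol mixtures, each with its nominal alcohol
#' content in vol %. Three liquors — red wine, imo-shochu and whisky — are
#' flagged `known = FALSE`: they are held out of training and used only to
#' test prediction on unseen samples.
#'
#' The `flavor_scale` column controls how strongly the synthetic generator
#' perturbs a sample with flavour components: 1 for beverages (full flavour
#' complexity), 0.1 for plain waters and buffer (trace impurities), and 0 for
#' ultrapure water and the binary water/ethanol mixtures.
#'
#' @return A data.frame with columns `name`, `alcohol_content` (vol %),
#'   `known` (logical) and `flavor_scale`.
#' @examples
#' tab <- default_sample_table()
#' nrow(tab)            # 35
#' sum(!tab$known)      # 3 held-out liquors
#' @export
default_sample_table <- function() {
  named <- data.frame(
    name = c("ultrapure water", "bottled water", "tap water", "PBS",
             "green tea", "oolong tea", "shochu and green tea", "beer",
             "shochu and oolong tea", "sangria", "ume-shu", "red wine",
             "junmai ryori-shu", "mirin", "japanese sake", "shoko-shu",
             "mugi-shochu", "cassis liqueur", "plant worm-shochu",
             "imo-shochu", "vodka", "gin", "palinka", "rum", "brandy",
             "whisky"),
    alcohol_content = c(0, 0, 0, 0, 0, 0, 4, 5, 6, 9, 12, 12, 14, 14.5, 15,
                        17.5, 20, 20, 25, 25, 40, 40, 40, 40, 40, 40),
    stringsAsFactors = FALSE
  )
  mix_pct <- seq(5, 45, by = 5)
  mixtures <- data.frame(
    name = sprintf("water/EtOH %d/%d", 100 - mix_pct, mix_pct),
    alcohol_content = as.numeric(mix_pct),
    stringsAsFactors = FALSE
  )
  tab <- rbind(named, mixtures)
  tab$known <- !(tab$name %in% c("red wine", "imo-shochu", "whisky"))
  tab$flavor_scale <- 1
  tab$flavor_scale[tab$name %in% c("bottled water", "tap water", "PBS")] <- 0.1
  tab$flavor_scale[tab$name == "ultrapure water"] <- 0
  tab$flavor_scale[grepl("^water/EtOH", tab$name)] <- 0
  tab
}

#' Component concentrations for a sample table
#'
#' Expands a sample table into per-sample headspace component concentrations
#' over the generator's component library: ethanol, water and `n_flavors`
#' flavour components. Ethanol concentration equals the alcohol content in
#' vol % (strictly monotone in it); water varies only weakly with alcohol
#' content, reflecting the near-saturated water vapour above aqueous samples;
#' flavour concentrations are log-normal per sample, scaled by the sample's
#' `flavor_scale`, so that samples of equal alcohol content still differ.
#'
#' @param samples Data.frame as returned by [default_sample_table()].
#' @param n_flavors Number of flavour components in the library.
#' @param seed Integer seed making the flavour draw reproducible.
#' @param flavor_meanlog,flavor_sdlog Log-normal parameters of the flavour
#'   concentration distribution (arbitrary units).
#' @return A numeric matrix, one row per sample, with columns
#'   `ethanol`, `water`, `flavor1` ... `flavor<n>`.
#' @export
sample_components <- function(samples, n_flavors = 6, seed = 1,
                              flavor_meanlog = log(5), flavor_sdlog = 0.8) {
  stopifnot(is.data.frame(samples), n_flavors >= 0)
  if (anyDuplicated(samples$name)) stop("duplicate sample names in sample table")
  n <- nrow(samples)
  fs <- samples$flavor_scale %||% rep(1, n)
  flav <- with_seed(seed, {
    matrix(stats::rlnorm(n * n_flavors, flavor_meanlog, flavor_sdlog),
           nrow = n, ncol = n_flavors)
  })
  flav <- flav * fs
  comp <- cbind(
    ethanol = samples$alcohol_content,
    water = 90 + 0.1 * (100 - samples$alcohol_content),
    flav
  )
  if (n_flavors > 0)
    colnames(comp)[-(1:2)] <- paste0("flavor", seq_len(n_flavors))
  rownames(comp) <- samples$name
  comp
}
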