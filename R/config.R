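#' Pipeline configuration
#'
#' All tunable parameters of the scoring pipeline with their defaults.
#' Override any subset by name, e.g.
#' `bseeg_config(bseeg = list(log10 = FALSE))` — unnamed entries keep their
#' defaults. [read_config()] loads overrides from a YAML file with the same
#' nesting.
#'
#' Defaults: band-pass 0.5–20 Hz (order-4 Butterworth, zero phase); QC
#' rejects windows with |amplitude| > 200 µV, variance < 2 µV²
#' (flatline — set above zero-phase filter ringing, which leaks up to
#' ~1 µV² into a dead span from adjacent signal), or more than half their
#' power above 15 Hz; 4-s windows feed
#' the spectral (BSEEG) score and 2-s windows the topological (TDA) score;
#' a subject-channel needs at least 30 s of passed windows to be scored.
#'
#' @param ... Named nested lists overriding defaults, e.g.
#'   `filter = list(order = 2)`.
#' @return A nested list of class `bseeg_config`.
#' @export
bseeg_config <- function(...) {
  cfg <- list(
    filter = list(low_cut = 0.5, high_cut = 20, order = 4),
    qc = list(max_abs_amplitude_uv = 200, min_variance = 2,
              max_high_band_fraction = 0.5, high_band_hz = 15),
    windows = list(bseeg_seconds = 4, tda_seconds = 2),
    usable_min_seconds = 30,
    bseeg = list(low_hz = 3, high_hz = 10, log10 = TRUE,
                 band_average = FALSE, taper = "rectangular",
                 aggregate = "median"),
    tda = list(embed_dim = 3, embed_lag = NULL, normalize = TRUE,
               max_filtration = "auto", grid_size = 200, max_points = 400,
               aggregate = "median", center_offset = 0,
               decimate_to_hz = 125)
  )
  cfg <- utils::modifyList(cfg, list(...))
  class(cfg) <- "bseeg_config"
  cfg
}

#' @rdname bseeg_config
#' @param path Path to a YAML file whose keys mirror the config structure.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config file: ", path)
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) overrides <- list()
  do.call(bseeg_config, overrides)
}
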