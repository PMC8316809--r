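#' Gate configuration
#'
#' Rectangular threshold gates for event tables: an event is counted as a
#' cell when its size proxy (`fsc`) and chlorophyll proxy (`fl3`) both sit at
#' or above their minima, which removes debris and dead cells from counts.
#' Gated events with `green >= green_min` are classified as GFP-tagged.
#'
#' @param fsc_min,fl3_min Minimum size and chlorophyll channel values for an
#'   event to count as a cell.
#' @param green_min Minimum green channel value for a gated event to count as
#'   GFP-tagged.
#' @param sample_volume Volume of culture sampled per acquisition (ml), used
#'   to convert event counts to densities.
#' @return A list of class `gate_config`.
#' @export
gate_config <- function(fsc_min = 100, fl3_min = 50, green_min = 50,
                        sample_volume = 0.05) {
  vals <- c(fsc_min = fsc_min, fl3_min = fl3_min, green_min = green_min)
  if (any(!is.finite(vals) & vals != Inf) || any(vals < 0))
    abort_domain("thresholds", "must be non-negative")
  if (!is.finite(sample_volume) || sample_volume <= 0)
    abort_domain("sample_volume", "must be a positive volume in ml")
  structure(list(fsc_min = fsc_min, fl3_min = fl3_min, green_min = green_min,
                 sample_volume = sample_volume), class = "gate_config")
}

check_channels <- function(events, needed) {
  missing <- setdiff(needed, names(events))
  if (length(missing) > 0)
    stop("event table is missing channel column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

#' Gate an event table
#'
#' Retains events with `fsc >= fsc_min` and `fl3 >= fl3_min` and converts the
#' retained count to a density using the sampled volume.
#'
#' @param events Tibble with at least `fsc` and `fl3` columns.
#' @param gates A [gate_config()].
#' @return A list with `count` (retained events), `density` (cells ml^-1)
#'   and `events` (the retained rows).
#' @export
gate_events <- function(events, gates = gate_config()) {
  stopifnot(inherits(gates, "gate_config"))
  check_channels(events, c("fsc", "fl3"))
  if (nrow(events) == 0) {
    warning("empty event table: density 0", call. = FALSE)
    return(list(count = 0L, density = 0, events = events))
  }
  keep <- events$fsc >= gates$fsc_min & events$fl3 >= gates$fl3_min
  kept <- events[keep, , drop = FALSE]
  list(count = nrow(kept), density = nrow(kept) / gates$sample_volume,
       events = kept)
}

#' Split gated events into wild-type and GFP populations
#'
#' Direct co-cultures track a wild-type focal lineage alongside a GFP-tagged
#' partner; after gating, the green channel separates the two. Counts always
#' partition: wild-type plus GFP equals the gated total.
#'
#' @param gated Result of [gate_events()], or a tibble of already-gated
#'   events.
#' @param gates A [gate_config()].
#' @return A list with `wildtype_count`, `gfp_count`, `wildtype_density` and
#'   `gfp_density`.
#' @export
classify_gfp <- function(gated, gates = gate_config()) {
  stopifnot(inherits(gates, "gate_config"))
  events <- if (is.data.frame(gated)) gated else gated$events
  check_channels(events, "green")
  is_gfp <- events$green >= gates$green_min
  list(wildtype_count = sum(!is_gfp), gfp_count = sum(is_gfp),
       wildtype_density = sum(!is_gfp) / gates$sample_volume,
       gfp_density = sum(is_gfp) / gates$sample_volume)
}
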