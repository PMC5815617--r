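#' Terrain classes
#'
#' The three cross-slope terrain classes used throughout the package, in the
#' fixed canonical order \code{eversion} (-15 degrees), \code{flush}
#' (0 degrees), \code{inversion} (+15 degrees). The canonical order is also
#' the deterministic tie-break order for classifier decisions.
#'
#' @return Character vector of the three class labels in canonical order.
#' @export
#' @examples
#' terrain_levels()
#' terrain_slope("inversion")
terrain_levels <- function() c("eversion", "flush", "inversion")

#' @rdname terrain_levels
#' @param label Character vector of terrain labels.
#' @return \code{terrain_slope}: cross-slope angle in degrees for each label.
#' @export
terrain_slope <- function(label) {
  slopes <- c(eversion = -15, flush = 0, inversion = 15)
  bad <- setdiff(unique(label), names(slopes))
  if (length(bad)) {
    stop("unknown terrain label(s): ", paste(bad, collapse = ", "))
  }
  unname(slopes[label])
}

#' @rdname terrain_levels
#' @param slope_deg Numeric vector of slopes; must be -15, 0 or +15.
#' @return \code{terrain_from_slope}: terrain label for each slope.
#' @export
terrain_from_slope <- function(slope_deg) {
  labels <- c(`-15` = "eversion", `0` = "flush", `15` = "inversion")
  key <- as.character(slope_deg)
  if (any(!key %in% names(labels))) {
    stop("slope must be one of -15, 0, +15 degrees")
  }
  unname(labels[key])
}

#' Coerce labels to a terrain factor
#'
#' @param label Character vector of terrain labels.
#' @return Factor with levels \code{terrain_levels()}.
#' @export
terrain_factor <- function(label) {
  bad <- setdiff(unique(as.character(label)), terrain_levels())
  if (length(bad)) {
    stop("unknown terrain label(s): ", paste(bad, collapse = ", "))
  }
  factor(as.character(label), levels = terrain_levels())
}
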