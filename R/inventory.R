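#' Signal inventories
#'
#' A signal inventory is the ordered registry of input signals available to
#' the classifier, together with each signal's source (motion capture or
#' in-pylon sensor package) and its per-window statistic policy. Kinematic,
#' moment and power signals contribute four statistics per analysis window
#' (mean, standard deviation, maximum, minimum); ground reaction force (GRF)
#' and center of pressure (COP) signals contribute two (mean, standard
#' deviation).
#'
#' Three variants are provided:
#' \describe{
#'   \item{\code{full_with_ips}}{28 four-statistic signals (ankle angles,
#'     angular velocities, angular accelerations, moments and powers in the
#'     flexion and inversion planes; foot linear velocity, linear acceleration
#'     and angular velocity along anteroposterior (AP), mediolateral (ML) and
#'     vertical axes; shank linear velocity; in-pylon accelerations and
#'     angular velocities) plus 6 two-statistic GRF/COP signals: 124 features
#'     per window.}
#'   \item{\code{full_mc_only}}{as above but the six in-pylon channels are
#'     replaced by motion-capture shank linear acceleration and shank angular
#'     velocity: again 124 features.}
#'   \item{\code{ips_only}}{only the six in-pylon channels (tri-axial
#'     acceleration AP/InfSup/ML and angular velocity in the coronal,
#'     sagittal and transverse planes): 24 features.}
#' }
#'
#' Motion-capture axes are lab-frame AP/ML/vertical; in-pylon axes are
#' shank-fixed. The ML axis is taken to point laterally for every subject so
#' left- and right-side amputees share one sign convention.
#'
#' @param variant One of \code{"full_with_ips"}, \code{"full_mc_only"},
#'   \code{"ips_only"}.
#' @return An object of class \code{signal_inventory}: a data frame with
#'   columns \code{name}, \code{source} (\code{motion_capture} or
#'   \code{in_pylon}) and \code{stat_policy} (\code{four_stats} or
#'   \code{two_stats}), plus attributes \code{variant} and \code{n_features}.
#' @export
#' @examples
#' inv <- signal_inventory("ips_only")
#' n_features(inv)  # 24
signal_inventory <- function(variant = c("full_with_ips", "full_mc_only",
                                         "ips_only")) {
  variant <- match.arg(variant)
  ankle <- paste0("ankle_", c(
    "flexion_angle", "inversion_angle",
    "flexion_angvel", "inversion_angvel",
    "flexion_angacc", "inversion_angacc",
    "flexion_moment", "inversion_moment",
    "flexion_power", "inversion_power"))
  axes3 <- c("ap", "ml", "vert")
  foot <- c(paste0("foot_", axes3, "_velocity"),
            paste0("foot_", axes3, "_acc"),
            paste0("foot_", axes3, "_angvel"))
  shank_vel <- paste0("shank_", axes3, "_velocity")
  ips <- c(paste0("ips_", c("ap", "infsup", "ml"), "_acc"),
           paste0("ips_", c("cor", "sag", "tran"), "_angvel"))
  shank_mc <- c(paste0("shank_", axes3, "_acc"),
                paste0("shank_", axes3, "_angvel"))
  grf_cop <- c(paste0("grf_", axes3), paste0("cop_", axes3))

  if (variant == "ips_only") {
    name <- ips
    source <- rep("in_pylon", 6L)
    policy <- rep("four_stats", 6L)
  } else {
    extra <- if (variant == "full_with_ips") ips else shank_mc
    extra_src <- if (variant == "full_with_ips") "in_pylon" else "motion_capture"
    name <- c(ankle, foot, shank_vel, extra, grf_cop)
    source <- c(rep("motion_capture", length(ankle) + length(foot) +
                      length(shank_vel)),
                rep(extra_src, 6L), rep("motion_capture", 6L))
    policy <- c(rep("four_stats", 28L), rep("two_stats", 6L))
  }
  inv <- data.frame(name = name, source = source, stat_policy = policy,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(inv$name)) stop("duplicate signal names in inventory")
  n_four <- sum(inv$stat_policy == "four_stats")
  n_two <- sum(inv$stat_policy == "two_stats")
  nf <- 4L * n_four + 2L * n_two
  expected <- c(full_with_ips = 124L, full_mc_only = 124L, ips_only = 24L)
  if (nf != expected[[variant]]) {
    stop("inventory '", variant, "' has ", nf, " features, expected ",
         expected[[variant]])
  }
  structure(inv, class = c("signal_inventory", "data.frame"),
            variant = variant, n_features = nf)
}

#' @rdname signal_inventory
#' @param inventory A \code{signal_inventory}.
#' @return \code{n_features}: integer feature count (124 or 24).
#' @export
n_features <- function(inventory) {
  stopifnot(inherits(inventory, "signal_inventory"))
  attr(inventory, "n_features")
}

#' @rdname signal_inventory
#' @export
inventory_variant <- function(inventory) {
  stopifnot(inherits(inventory, "signal_inventory"))
  attr(inventory, "variant")
}

# internal: wrap an arbitrary signal table as an inventory (used when
# restricting to a signal subset); feature-count bookkeeping only.
new_signal_inventory <- function(df, variant = "custom") {
  stopifnot(all(c("name", "source", "stat_policy") %in% names(df)))
  if (anyDuplicated(df$name)) stop("duplicate signal names in inventory")
  nf <- 4L * sum(df$stat_policy == "four_stats") +
    2L * sum(df$stat_policy == "two_stats")
  structure(as.data.frame(df, stringsAsFactors = FALSE),
            class = c("signal_inventory", "data.frame"),
            variant = variant, n_features = nf)
}

#' Per-window statistic names for one signal
#'
#' @param policy \code{"four_stats"} or \code{"two_stats"}.
#' @return Character vector of statistic names in the fixed order
#'   mean, sd, max, min (truncated to mean, sd for two-statistic signals).
#' @export
stat_names <- function(policy = c("four_stats", "two_stats")) {
  policy <- match.arg(policy)
  if (policy == "four_stats") c("mean", "sd", "max", "min") else c("mean", "sd")
}

#' Feature column keys of an inventory
#'
#' Deterministic feature ordering: inventory order crossed with statistic
#' order, as \code{"<signal>.<stat>"}.
#'
#' @param inventory A \code{signal_inventory}.
#' @return Character vector of length \code{n_features(inventory)}.
#' @export
feature_keys <- function(inventory) {
  stopifnot(inherits(inventory, "signal_inventory"))
  unlist(lapply(seq_len(nrow(inventory)), function(i) {
    paste(inventory$name[i], stat_names(inventory$stat_policy[i]), sep = ".")
  }), use.names = FALSE)
}
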