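#' Condition profile: algorithm parameters for a gait/path/limb combination
#'
#' Bundles the detector settings that depend on the movement condition. The
#' defaults encode the validated parameter set: a resultant-velocity foot-on
#' threshold of 0.5 m/s everywhere except the inside limbs on the circle at
#' trot (1.0 m/s fore, 1.2 m/s hind, compensating an impact-mechanics bias);
#' vertical acceleration filtered at 25 Hz (trot) or 20 Hz (walk) for the
#' acceleration-peak foot-on detector, switching to resultant acceleration at
#' 15 Hz for the hind limbs on the circle at trot; and a 15 Hz cut-off for the
#' vertical-velocity foot-off detector at both gaits.
#'
#' @param gait "walk" or "trot".
#' @param path "straight" or "circle".
#' @param limb "fore" or "hind".
#' @param circle_side "inside", "outside", or "n/a" (required iff on circle).
#' @param v_threshold,accel_component,accel_cutoff_hz,vvel_cutoff_hz override
#'   the condition-derived defaults.
#' @return An object of class `condition_profile`.
#' @export
condition_profile <- function(gait, path, limb, circle_side = "n/a",
                              v_threshold = NULL, accel_component = NULL,
                              accel_cutoff_hz = NULL, vvel_cutoff_hz = NULL) {
  gait <- match.arg(gait, c("walk", "trot"))
  path <- match.arg(path, c("straight", "circle"))
  limb <- match.arg(limb, c("fore", "hind"))
  circle_side <- match.arg(circle_side, c("inside", "outside", "n/a"))
  if (path == "straight" && circle_side != "n/a")
    stop("`circle_side` must be \"n/a\" on the straight", call. = FALSE)
  if (path == "circle" && circle_side == "n/a")
    stop("`circle_side` is required on the circle", call. = FALSE)

  if (is.null(v_threshold)) {
    v_threshold <- 0.5
    if (gait == "trot" && path == "circle" && circle_side == "inside")
      v_threshold <- if (limb == "fore") 1.0 else 1.2
  }
  if (is.null(accel_component)) {
    accel_component <-
      if (limb == "hind" && path == "circle" && gait == "trot") "resultant"
      else "vertical"
  }
  accel_component <- match.arg(accel_component, c("vertical", "resultant"))
  if (is.null(accel_cutoff_hz)) {
    accel_cutoff_hz <-
      if (accel_component == "resultant") 15
      else if (gait == "trot") 25 else 20
  }
  if (is.null(vvel_cutoff_hz)) vvel_cutoff_hz <- 15
  if (v_threshold <= 0 || accel_cutoff_hz <= 0 || vvel_cutoff_hz <= 0)
    stop("thresholds and cut-offs must be positive", call. = FALSE)

  structure(
    list(gait = gait, path = path, limb = limb, circle_side = circle_side,
         v_threshold = v_threshold, accel_component = accel_component,
         accel_cutoff_hz = accel_cutoff_hz, vvel_cutoff_hz = vvel_cutoff_hz),
    class = "condition_profile"
  )
}

#' @export
print.condition_profile <- function(x, ...) {
  side <- if (x$circle_side == "n/a") "" else paste0(", ", x$circle_side)
  cat(sprintf(
    "<condition_profile> %s %s, %s limb%s\n  v_threshold %.1f m/s | accel %s @ %g Hz | vvel @ %g Hz\n",
    x$gait, x$path, x$limb, side, x$v_threshold, x$accel_component,
    x$accel_cutoff_hz, x$vvel_cutoff_hz))
  invisible(x)
}

#' Resolve a condition profile from limb side and rein
#'
#' On the circle, whether a limb is on the inside or outside depends on the
#' rein (direction of travel): on the right rein (clockwise) the left limbs
#' are on the outside, on the left rein (anti-clockwise) they are on the
#' inside, mirrored for the right limbs. This mapping also defines which limb
#' pair shares a loading condition when pooling method differences across
#' reins.
#'
#' @param gait "walk" or "trot".
#' @param path "straight" or "circle".
#' @param limb "fore" or "hind".
#' @param limb_side "left" or "right" (required on the circle).
#' @param rein "left", "right", or "n/a"; must be "n/a" iff `path` is
#'   "straight".
#' @return A [condition_profile()].
#' @export
#' @examples
#' resolve_condition_profile("trot", "circle", "hind",
#'                           limb_side = "left", rein = "left")
resolve_condition_profile <- function(gait, path, limb, limb_side = NULL,
                                      rein = "n/a") {
  path <- match.arg(path, c("straight", "circle"))
  if (path == "straight") {
    if (!rein %in% c("n/a", NA))
      stop("`rein` must be \"n/a\" on the straight", call. = FALSE)
    return(condition_profile(gait, path, limb, circle_side = "n/a"))
  }
  rein <- match.arg(rein, c("left", "right"))
  limb_side <- match.arg(limb_side, c("left", "right"))
  circle_side <- if (limb_side == rein) "inside" else "outside"
  condition_profile(gait, path, limb, circle_side = circle_side)
}
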