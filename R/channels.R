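#' Canonical accelerometer channels
#'
#' The pipeline consumes six acceleration channels from two body-worn
#' inertial units: chest and hand, three axes each. Channel identifiers are
#' strings of the form `"<location>_a<axis>"` (e.g. `"chest_az"`), and the
#' canonical column order is chest x, y, z followed by hand x, y, z.
#'
#' @param location Optional, `"chest"` or `"hand"`; restricts the returned
#'   channels to one sensor location.
#' @return Character vector of channel identifiers in canonical order.
#' @export
#' @examples
#' canonical_channels()
#' canonical_channels("hand")
canonical_channels <- function(location = c("chest", "hand")) {
  location <- match.arg(location, several.ok = TRUE)
  paste0(rep(location, each = 3L), "_a", rep(c("x", "y", "z"), length(location)))
}

#' Build a channel identifier
#'
#' @param location `"chest"` or `"hand"`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return A channel identifier string, e.g. `"chest_az"`.
#' @export
channel_id <- function(location, axis) {
  location <- match.arg(location, c("chest", "hand"))
  axis <- match.arg(axis, c("x", "y", "z"))
  paste0(location, "_a", axis)
}

#' Activity classes
#'
#' Fixed four-class label set, in the index order used throughout the
#' package (classifier outputs, soft labels, confusion tallies):
#' break, dip, pullup, squat. `break` is the non-exercise class.
#'
#' @return Character vector of the four activity labels.
#' @export
activity_levels <- function() {
  c("break", "dip", "pullup", "squat")
}

#' @rdname activity_levels
#' @return `exercise_levels()` returns the three non-break labels.
#' @export
exercise_levels <- function() {
  c("dip", "pullup", "squat")
}

#' Informative channels per activity
#'
#' The channels on which each exercise produces its dominant repetition
#' waveform, as identified by the study's per-channel signal-energy
#' screening: dips on chest z, hand x and hand z; pull-ups on chest y,
#' chest z and hand z; squats on chest z only. These are also the channels
#' the repetition counter reads by default.
#'
#' @param activity `"dip"`, `"pullup"` or `"squat"`.
#' @return Character vector of channel identifiers.
#' @export
#' @examples
#' informative_channels("dip")
informative_channels <- function(activity) {
  activity <- match.arg(activity, exercise_levels())
  switch(activity,
    dip    = c("chest_az", "hand_ax", "hand_az"),
    pullup = c("chest_ay", "chest_az", "hand_az"),
    squat  = "chest_az"
  )
}
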