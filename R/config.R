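#' Restraint ramp schedule
#'
#' Step schedule of the scale factor applied to the artificial disulfide
#' restraints: alpha = k / n_steps, with k incremented once per window of
#' \code{step_duration} picoseconds.  The defaults (200 steps of 10 ps)
#' ramp the restraints from 1/200 of full strength to full strength over a
#' 2-ns segment.  \code{ramp_scale(s, 0)} is exactly 0 and
#' \code{ramp_scale(s, n_steps)} exactly 1, but the first scale actually
#' applied during a ramp is \code{ramp_scale(s, 1)} = 1/200.
#'
#' @param n_steps number of ramp windows (default 200)
#' @param step_duration window length, ps (default 10)
#' @return an object of class \code{ramp_schedule}
#' @export
ramp_schedule <- function(n_steps = 200, step_duration = 10) {
  stopifnot(n_steps >= 1, step_duration > 0)
  structure(list(n_steps = as.integer(n_steps),
                 step_duration = step_duration),
            class = "ramp_schedule")
}

#' @rdname ramp_schedule
#' @param schedule a \code{ramp_schedule}
#' @param k window index, 0..n_steps
#' @return the dimensionless scale factor alpha
#' @export
ramp_scale <- function(schedule, k) {
  if (any(k < 0) || any(k > schedule$n_steps))
    stop("ramp window index out of range")
  k / schedule$n_steps
}

#' Controller configuration
#'
#' Parameters of the reactive folding protocol.  Defaults are the original
#' protocol values: capture radius 2.5 A, every thiol encounter productive
#' (accept_prob = 1; the reduced-reactivity variant uses 0.001 per contact
#' frame), 1-ns segments with frames stored every 1 ps, temperature 293 K,
#' Langevin collision frequency 2/ps, integration step 2 fs.  Stage lengths
#' default to desk-scale values for the coarse-grained fixture
#' (1 ns equilibration / 10 ns maximum folding / 1 ns extension);
#' full-scale stage lengths typical of all-atom studies of this system are
#' available as \code{stage_preset("reference")}.
#'
#' @param capture_radius S-S distance (A) that triggers the bonding
#'   procedure
#' @param accept_prob per-contact-frame acceptance probability of the
#'   stochastic reactivity gate, in (0, 1]
#' @param segment_length length (ps) of one monitored simulation segment
#' @param frame_interval spacing (ps) of stored frames; must divide
#'   \code{segment_length}
#' @param lj_mode \code{"masked"} or \code{"shrunk_r0"} (see
#'   \code{\link{lj_params}}); the capture radius is kept at 2.5 A in both
#'   modes
#' @param stage_lengths named numeric vector (ps):
#'   \code{equilibration}, \code{folding} (maximum), \code{extension}
#' @param seed integer seed for the run (gate decisions and, unless the
#'   start frame carries its own RNG state, the dynamics stream)
#' @param temperature thermostat temperature, K
#' @param gamma Langevin collision frequency, 1/ps
#' @param dt integration step, ps
#' @param ramp a \code{\link{ramp_schedule}}
#' @return an object of class \code{controller_config}
#' @export
controller_config <- function(capture_radius = 2.5, accept_prob = 1.0,
                              segment_length = 1000, frame_interval = 1,
                              lj_mode = c("masked", "shrunk_r0"),
                              stage_lengths = c(equilibration = 1000,
                                                folding = 10000,
                                                extension = 1000),
                              seed = 1, temperature = 293, gamma = 2,
                              dt = 0.002, ramp = ramp_schedule()) {
  lj_mode <- match.arg(lj_mode)
  if (!(accept_prob > 0 && accept_prob <= 1))
    stop("config error: accept_prob must be in (0, 1]")
  if (capture_radius >= lj_params()$r0)
    stop("config error: capture_radius must be below the unmasked LJ r0")
  if (abs(segment_length / frame_interval -
          round(segment_length / frame_interval)) > 1e-9)
    stop("config error: frame_interval must divide segment_length")
  stopifnot(length(stage_lengths) == 3, all(stage_lengths >= 0),
            temperature >= 0, gamma >= 0, dt > 0)
  names(stage_lengths) <- c("equilibration", "folding", "extension")
  structure(list(capture_radius = capture_radius, accept_prob = accept_prob,
                 segment_length = segment_length,
                 frame_interval = frame_interval, lj_mode = lj_mode,
                 stage_lengths = stage_lengths, seed = as.integer(seed),
                 temperature = temperature, gamma = gamma, dt = dt,
                 ramp = ramp), class = "controller_config")
}

#' Preset stage lengths
#'
#' \code{"desk"}: 1 ns / 10 ns / 1 ns, suitable for the coarse-grained
#' fixture.  \code{"reference"}: 100 ns equilibration, up to 1 microsecond
#' of folding, 450 ns extension — full-scale conditions for all-atom
#' studies of this system.
#'
#' @param name \code{"desk"} or \code{"reference"}
#' @return named numeric vector of stage lengths, ps
#' @export
stage_preset <- function(name = c("desk", "reference")) {
  switch(match.arg(name),
         desk = c(equilibration = 1000, folding = 10000, extension = 1000),
         reference = c(equilibration = 1e5, folding = 1e6,
                       extension = 4.5e5))
}

#' Disulfide reduction configuration
#'
#' Optional reverse step: at each segment boundary every existing disulfide
#' is reduced with probability \code{base_prob * exposure(pair)}.  The
#' exposure proxy scales the reduction probability by the accessibility of
#' the bridge (intended to mimic access of a reducing agent):
#' \code{"constant"} is 1, \code{"inverse_neighbors"} is
#' \code{1 / (1 + n)} with \code{n} the number of non-bridge beads within
#' 6 A of the S-S midpoint.  Reduction is meant to be slow compared to
#' oxidation (\code{base_prob} well below the gate's accept_prob).
#'
#' @param enabled logical
#' @param base_prob per-decision base probability p_r
#' @param exposure_fn \code{"constant"} or \code{"inverse_neighbors"}
#' @return an object of class \code{reduction_config}
#' @export
reduction_config <- function(enabled = FALSE, base_prob = 0,
                             exposure_fn = c("constant",
                                             "inverse_neighbors")) {
  exposure_fn <- match.arg(exposure_fn)
  stopifnot(base_prob >= 0, base_prob <= 1)
  structure(list(enabled = isTRUE(enabled), base_prob = base_prob,
                 exposure_fn = exposure_fn), class = "reduction_config")
}

.exposure <- function(fn, top, frame, pair) {
  switch(fn,
         constant = 1,
         inverse_neighbors = {
           mid <- colMeans(frame$positions[pair, , drop = FALSE])
           host <- c(.sg_host(top, pair[1]), .sg_host(top, pair[2]))
           others <- setdiff(seq_len(top$n_particles), c(pair, host))
           d <- sqrt(colSums((t(frame$positions[others, , drop = FALSE]) -
                                mid)^2))
           1 / (1 + sum(d < 6))
         })
}

#' @export
print.controller_config <- function(x, ...) {
  cat("Reactive controller configuration\n")
  cat(sprintf("  capture radius: %.3g A, gate accept prob: %g, LJ mode: %s\n",
              x$capture_radius, x$accept_prob, x$lj_mode))
  cat(sprintf("  segments: %g ps (frames every %g ps)\n",
              x$segment_length, x$frame_interval))
  cat(sprintf("  stages (ps): equilibration %g, folding %g, extension %g\n",
              x$stage_lengths[1], x$stage_lengths[2], x$stage_lengths[3]))
  cat(sprintf("  T = %g K, gamma = %g/ps, dt = %g ps, seed %d\n",
              x$temperature, x$gamma, x$dt, x$seed))
  cat(sprintf("  ramp: %d windows x %g ps\n", x$ramp$n_steps,
              x$ramp$step_duration))
  invisible(x)
}
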