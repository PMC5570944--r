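#' Construct a simulation frame
#'
#' A frame is the unit of trajectory storage and replay: simulation time
#' (ps), per-particle positions (A) and velocities (A/ps), and the 32-byte
#' state of the dynamics RNG sufficient for bitwise replay of everything
#' that follows.
#'
#' @param time simulation time, ps (non-negative)
#' @param positions n x 3 numeric matrix, A
#' @param velocities n x 3 numeric matrix, A/ps
#' @param rng_state raw vector of length 32 (see \code{\link{seed_rng}})
#' @return an object of class \code{cg_frame}
#' @export
new_frame <- function(time, positions, velocities = NULL, rng_state = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (time < 0) stop("time must be non-negative")
  if (is.null(velocities))
    velocities <- matrix(0, nrow(positions), 3)
  velocities <- as.matrix(velocities)
  dimnames(positions) <- NULL
  dimnames(velocities) <- NULL
  structure(list(time = as.numeric(time), positions = positions,
                 velocities = velocities, rng_state = rng_state),
            class = "cg_frame")
}

#' Seed the dynamics RNG
#'
#' Returns the 32-byte state of the engine's own xoshiro256++ stream.  The
#' stream is independent of R's RNG (which drives the controller's gate
#' decisions), so a stored frame state replays the dynamics bitwise.
#'
#' @param seed non-negative integer seed
#' @return raw vector of length 32
#' @export
seed_rng <- function(seed) {
  rng_seed_cpp(as.numeric(seed))
}

#' Maxwell-Boltzmann velocities
#'
#' Draws per-particle velocities at the given temperature using R's RNG
#' (seed before calling for reproducibility).
#'
#' @param masses particle masses, amu
#' @param temperature K
#' @return n x 3 matrix of velocities, A/ps
#' @export
maxwell_velocities <- function(masses, temperature = 293) {
  n <- length(masses)
  sd <- sqrt(.kB * temperature * .acc / masses)
  matrix(rnorm(3 * n, sd = rep(sd, 3)), n, 3)
}

#' Instantaneous kinetic temperature
#'
#' Equipartition estimate \eqn{T = 2 KE / (3 N k_B)} from the velocities of
#' a frame.
#'
#' @param frame a \code{cg_frame}
#' @param masses particle masses, amu
#' @return temperature, K
#' @export
kinetic_temperature <- function(frame, masses) {
  ke <- 0.5 * sum(masses * rowSums(frame$velocities^2)) / .acc # kcal/mol
  2 * ke / (3 * nrow(frame$positions) * .kB)
}

#' @export
print.cg_frame <- function(x, ...) {
  cat("Frame at t =", x$time, "ps,", nrow(x$positions), "particles\n")
  invisible(x)
}
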