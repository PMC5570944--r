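# R-side interface to the C++ force/integration kernel.

# Flatten topology + restraints into the plain lists consumed by the kernel.
# `extra_mask` holds additional LJ-disabled pairs (the prospective bonded
# neighbourhood while a ramp is active).
.ff_list <- function(top, extra_mask = NULL) {
  n <- top$n_particles
  status <- matrix(1L, n, n)
  diag(status) <- 0L
  zero_pairs <- rbind(top$exclusions, if (top$mask_active &&
                                          top$lj_mode == "masked")
    top$lj_mask, .pair_mat(extra_mask))
  if (nrow(zero_pairs)) {
    status[zero_pairs] <- 0L
    status[zero_pairs[, c(2, 1), drop = FALSE]] <- 0L
  }
  if (top$mask_active && top$lj_mode == "shrunk_r0") {
    rp <- reactive_pairs(top)
    if (nrow(rp)) {
      keep <- status[rp] != 0L
      rp <- rp[keep, , drop = FALSE]
      status[rp] <- 2L
      status[rp[, c(2, 1), drop = FALSE]] <- 2L
    }
  }
  list(mass = top$particles$mass,
       bond_i = top$bonds$i, bond_j = top$bonds$j,
       bond_k = top$bonds$k, bond_r0 = top$bonds$r0,
       angle_i = top$angles$i, angle_j = top$angles$j,
       angle_k = top$angles$k, angle_kf = top$angles$kf,
       angle_t0 = .deg2rad(top$angles$theta0),
       dihedral_i = top$dihedrals$i, dihedral_j = top$dihedrals$j,
       dihedral_k = top$dihedrals$k, dihedral_l = top$dihedrals$l,
       dihedral_kf = top$dihedrals$kf,
       dihedral_p0 = .deg2rad(top$dihedrals$phi0),
       lj_eps = top$lj$epsilon, lj_r0 = top$lj$r0,
       lj_r0_shrunk = top$lj$r0_shrunk, lj_cutoff = top$lj$cutoff,
       lj_status = status, sphere_radius = top$sphere_radius)
}

.restraint_list <- function(restraints) {
  if (is.null(restraints))
    restraints <- restraint_set()
  list(dist_i = restraints$distance$i, dist_j = restraints$distance$j,
       dist_k = restraints$distance$k, dist_r0 = restraints$distance$r0,
       angle_i = restraints$angles$i, angle_j = restraints$angles$j,
       angle_k = restraints$angles$k, angle_kf = restraints$angles$kf,
       angle_t0 = .deg2rad(restraints$angles$theta0),
       dihedral_i = restraints$dihedrals$i,
       dihedral_j = restraints$dihedrals$j,
       dihedral_k = restraints$dihedrals$k,
       dihedral_l = restraints$dihedrals$l,
       dihedral_kf = restraints$dihedrals$kf,
       dihedral_p0 = .deg2rad(restraints$dihedrals$phi0))
}

#' Lennard-Jones pair energy
#'
#' Evaluates \eqn{\varepsilon ((r_0/r)^{12} - 2 (r_0/r)^6)}, truncated (not
#' shifted) at the cutoff.  A masked pair contributes exactly zero at any
#' distance.
#'
#' @param r pair distance(s), A (> 0)
#' @param params \code{\link{lj_params}}
#' @param masked logical: is this pair's LJ term disabled?
#' @return energy, kcal/mol (vectorized over \code{r})
#' @export
lj_pair_energy <- function(r, params = lj_params(), masked = FALSE) {
  if (any(r <= 0)) stop("invalid geometry: non-positive pair distance")
  if (isTRUE(masked)) return(rep(0, length(r)))
  sr6 <- (params$r0 / r)^6
  ifelse(r > params$cutoff, 0, params$epsilon * (sr6^2 - 2 * sr6))
}

#' Energy breakdown of a configuration
#'
#' Bond, angle, dihedral, Lennard-Jones and restraint energies plus their
#' total, honoring exclusions, the reactive-pair LJ mask, and any active
#' restraints scaled by alpha.
#'
#' @param frame a \code{cg_frame} (or n x 3 coordinate matrix)
#' @param top a \code{cg_topology}
#' @param restraints optional \code{restraint_set}
#' @param alpha restraint scale factor in [0, 1]
#' @param extra_mask optional additional LJ-disabled pairs (k x 2 matrix)
#' @return named list of energies (kcal/mol) with class
#'   \code{energy_breakdown}
#' @export
energy_breakdown <- function(frame, top, restraints = NULL, alpha = 0,
                             extra_mask = NULL) {
  pos <- if (inherits(frame, "cg_frame")) frame$positions else as.matrix(frame)
  out <- cg_compute_cpp(pos, .ff_list(top, extra_mask),
                        .restraint_list(restraints), alpha, FALSE)
  structure(out, class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("Energy (kcal/mol): bond %.4f  angle %.4f  dihedral",
                     " %.4f  LJ %.4f  restraint %.4f  total %.4f\n"),
              x$bond, x$angle, x$dihedral, x$lj, x$restraint, x$total))
  invisible(x)
}

#' Forces on all particles
#'
#' The exact negative gradient of the total energy (verified against central
#' finite differences in the package tests).
#'
#' @inheritParams energy_breakdown
#' @return n x 3 matrix of forces, kcal/mol/A
#' @export
compute_forces <- function(frame, top, restraints = NULL, alpha = 0,
                           extra_mask = NULL) {
  pos <- if (inherits(frame, "cg_frame")) frame$positions else as.matrix(frame)
  cg_compute_cpp(pos, .ff_list(top, extra_mask),
                 .restraint_list(restraints), alpha, TRUE)$forces
}

#' Advance one Langevin (BAOAB) step
#'
#' One step of the BAOAB splitting of Langevin dynamics.  With
#' \code{gamma = 0} the thermostat (O) step is skipped and the integrator
#' reduces exactly to velocity Verlet (NVE).  The frame's RNG state is
#' consumed and the successor frame records the advanced state, so an
#' identical frame always yields a bitwise-identical successor.
#'
#' @param frame a \code{cg_frame} with an RNG state (see
#'   \code{\link{seed_rng}}) unless \code{gamma = 0}
#' @param top a \code{cg_topology}
#' @param dt integration step, ps
#' @param gamma collision frequency, 1/ps
#' @param temperature K
#' @param restraints optional \code{restraint_set}
#' @param alpha restraint scale factor
#' @param extra_mask optional additional LJ-disabled pairs
#' @return the successor \code{cg_frame}
#' @export
langevin_step <- function(frame, top, dt = 0.002, gamma = 2,
                          temperature = 293, restraints = NULL, alpha = 0,
                          extra_mask = NULL) {
  seg <- run_segment(frame, top, length_ps = dt, frame_interval = dt,
                     dt = dt, gamma = gamma, temperature = temperature,
                     restraints = restraints, alpha = alpha,
                     extra_mask = extra_mask)
  seg$frames[[1]]
}

#' Propagate a trajectory segment
#'
#' Runs \code{length_ps / dt} BAOAB steps, storing a frame (positions,
#' velocities, RNG state) every \code{frame_interval} ps.  The returned
#' segment record carries its start frame and engine arguments so that it
#' can be replayed bitwise (see \code{\link{rewind_to_crossing}}).
#'
#' @inheritParams langevin_step
#' @param length_ps segment length, ps
#' @param frame_interval frame spacing, ps (must divide \code{length_ps})
#' @param segment_index integer label carried in the record
#' @return an object of class \code{cg_segment}: list with
#'   \code{start_frame}, \code{frames} (list of \code{cg_frame}),
#'   \code{segment_index}, \code{engine_args}
#' @export
run_segment <- function(frame, top, length_ps, frame_interval = 1,
                        dt = 0.002, gamma = 2, temperature = 293,
                        restraints = NULL, alpha = 0, extra_mask = NULL,
                        segment_index = 0L) {
  n_steps <- round(length_ps / dt)
  save_every <- round(frame_interval / dt)
  if (abs(n_steps * dt - length_ps) > 1e-9 ||
      abs(save_every * dt - frame_interval) > 1e-9 ||
      n_steps %% save_every != 0)
    stop("length_ps and frame_interval must be multiples of dt")
  rng <- frame$rng_state
  if (is.null(rng)) {
    if (gamma > 0) stop("frame has no RNG state; seed it with seed_rng()")
    rng <- seed_rng(0)
  }
  out <- cg_run_cpp(frame$positions, frame$velocities, .ff_list(top, extra_mask),
                    .restraint_list(restraints), alpha,
                    as.integer(n_steps), as.integer(save_every),
                    dt, gamma, temperature, rng)
  nf <- out$n_frames
  frames <- vector("list", nf)
  np <- nrow(frame$positions)
  for (f in seq_len(nf)) {
    frames[[f]] <- new_frame(time = frame$time + f * frame_interval,
                             positions = matrix(out$positions[, , f],
                                                np, 3),
                             velocities = matrix(out$velocities[, , f],
                                                 np, 3),
                             rng_state = out$rng[[f]])
  }
  structure(list(start_frame = frame, frames = frames,
                 segment_index = as.integer(segment_index),
                 engine_args = list(frame_interval = frame_interval, dt = dt,
                                    gamma = gamma,
                                    temperature = temperature,
                                    restraints = restraints, alpha = alpha,
                                    extra_mask = extra_mask)),
            class = "cg_segment")
}

#' @export
print.cg_segment <- function(x, ...) {
  cat("Trajectory segment", x$segment_index, "with", length(x$frames),
      "frames,", "t =", x$start_frame$time, "..",
      x$frames[[length(x$frames)]]$time, "ps\n")
  invisible(x)
}
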