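# Seeded generators of test systems: guanylin-like chains and the minimal
# two-bead / four-bead fixtures used for ramp and angle tests.

#' Specification of a synthetic peptide chain
#'
#' @param n_residues number of residues
#' @param reactive_positions distinct 1-based residue positions carrying a
#'   reactive cysteine (an even count is needed for full-folding tests)
#' @param bond_length backbone virtual-bond length, A
#' @param seed integer seed; the generator is a pure function of the spec
#' @return an object of class \code{chain_spec}
#' @export
chain_spec <- function(n_residues, reactive_positions, bond_length = 3.8,
                       seed = 1) {
  reactive_positions <- sort(as.integer(reactive_positions))
  if (anyDuplicated(reactive_positions) ||
      any(reactive_positions < 1) || any(reactive_positions > n_residues))
    stop("reactive positions must be distinct and within [1, n_residues]")
  stopifnot(bond_length > 0)
  structure(list(n_residues = as.integer(n_residues),
                 reactive_positions = reactive_positions,
                 bond_length = bond_length, seed = as.integer(seed)),
            class = "chain_spec")
}

#' Guanylin-like chain preset
#'
#' A 15-residue chain with reactive cysteines at positions 4, 7, 12 and 15,
#' mirroring mature guanylin's four cysteines.
#'
#' @param seed integer seed
#' @return a \code{\link{chain_spec}}
#' @export
guanylin_spec <- function(seed = 1) {
  chain_spec(15, c(4, 7, 12, 15), seed = seed)
}

# CG parameters of the generic chain.  One backbone bead per residue
# (110 amu) bonded at `bond_length`; a 32.06-amu sulfur bead 1.8 A off each
# cysteine backbone bead.  Backbone angles are soft so the chain stays
# flexible and disordered.
.bb_mass <- 110
.sg_mass <- 32.06
.bb_bond_k <- 100
.sg_bond_k <- 100
.sg_bond_r0 <- 1.8
.bb_angle_k <- 2
.bb_angle_t0 <- 120

.chain_topology <- function(spec, lj = lj_params(),
                            lj_mode = "masked", sphere_radius = 60) {
  n <- spec$n_residues
  labels <- rep("ALA", n)
  labels[spec$reactive_positions] <- "CYR"
  particles <- data.frame(name = rep("CA", n), resid = seq_len(n),
                          mass = rep(.bb_mass, n))
  bonds <- data.frame(i = seq_len(n - 1), j = 2:n, k = .bb_bond_k,
                      r0 = spec$bond_length)
  angles <- if (n >= 3)
    data.frame(i = seq_len(n - 2), j = 2:(n - 1), k = 3:n, kf = .bb_angle_k,
               theta0 = .bb_angle_t0)
  else NULL
  reactive <- integer()
  for (pos in spec$reactive_positions) {
    particles <- rbind(particles,
                       data.frame(name = "SG", resid = pos, mass = .sg_mass))
    sg <- nrow(particles)
    bonds <- rbind(bonds, data.frame(i = pos, j = sg, k = .sg_bond_k,
                                     r0 = .sg_bond_r0))
    reactive <- c(reactive, sg)
  }
  cg_topology(particles = particles, bonds = bonds, residue_labels = labels,
              angles = angles, reactive_sites = reactive, lj = lj,
              lj_mode = lj_mode, sphere_radius = sphere_radius)
}

#' Generate a random self-avoiding chain
#'
#' Builds the coarse-grained topology for the spec and draws a
#' self-avoiding random-walk conformation: backbone beads placed at fixed
#' bond length with no two non-bonded beads closer than a hard-core
#' distance, sulfur beads placed 1.8 A off their host with clash checks,
#' the chain centred at the origin, and Maxwell-Boltzmann velocities at the
#' given temperature.  Deterministic per seed (the generator is a pure
#' function of the spec).
#'
#' @param spec a \code{\link{chain_spec}}
#' @param temperature K, for the initial velocities
#' @param max_restarts bounded retries before a generation error
#' @return list with \code{topology} and \code{frame}
#' @export
random_chain <- function(spec, temperature = 293, max_restarts = 50) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  top <- .chain_topology(spec)
  n <- spec$n_residues
  core_bb <- 3.4   # hard-core distance between non-bonded backbone beads
  core_sg <- 2.0
  for (attempt in seq_len(max_restarts)) {
    bb <- matrix(NA_real_, n, 3)
    bb[1, ] <- 0
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      for (try in 1:100) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        cand <- bb[i - 1, ] + spec$bond_length * u
        prev <- bb[seq_len(i - 2), , drop = FALSE]
        if (nrow(prev) == 0 ||
            min(sqrt(rowSums((prev - rep(cand, each = nrow(prev)))^2))) >=
              core_bb) {
          bb[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (!ok) next
    # sulfur beads off their hosts
    sg_rows <- which(top$particles$name == "SG")
    pos <- matrix(NA_real_, top$n_particles, 3)
    pos[seq_len(n), ] <- bb
    for (sg in sg_rows) {
      host <- top$particles$resid[sg]
      placed <- FALSE
      for (try in 1:100) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        cand <- bb[host, ] + .sg_bond_r0 * u
        others <- pos[setdiff(which(!is.na(pos[, 1])), host), , drop = FALSE]
        if (nrow(others) == 0 ||
            min(sqrt(rowSums((others - rep(cand,
                                           each = nrow(others)))^2))) >=
              core_sg) {
          pos[sg, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (!ok) next
    pos <- sweep(pos, 2, colMeans(pos))
    vel <- maxwell_velocities(top$particles$mass, temperature)
    frame <- new_frame(0, pos, vel, rng_state = seed_rng(spec$seed))
    return(list(topology = top, frame = frame))
  }
  stop("generation error: could not place a self-avoiding chain after ",
       max_restarts, " restarts")
}

#' Minimal two-bead reactive system
#'
#' Two reactive sulfur beads at the given separation, no bonded terms, LJ
#' mask active.  The canonical fixture for capture detection and the
#' distance-restraint ramp.
#'
#' @param separation initial S-S distance, A
#' @param seed seed for the dynamics RNG state
#' @return list with \code{topology} and \code{frame}
#' @export
two_bead_system <- function(separation = 2.5, seed = 1) {
  particles <- data.frame(name = c("SG", "SG"), resid = 1:2,
                          mass = rep(.sg_mass, 2))
  top <- cg_topology(particles = particles,
                     bonds = NULL, residue_labels = c("CYR", "CYR"),
                     reactive_sites = 1:2)
  top <- set_lj_mask(top, TRUE)
  pos <- rbind(c(-separation / 2, 0, 0), c(separation / 2, 0, 0))
  list(topology = top,
       frame = new_frame(0, pos, rng_state = seed_rng(seed)))
}

#' Minimal four-bead C-S-S-C system
#'
#' Two cysteine backbone beads, each bonded to its sulfur; the sulfurs are
#' reactive (masked) and start at the given S-S distance with the given
#' C-S-S angles and C-S-S-C dihedral.  Particle order: C1, S2, S3, C4.
#'
#' @param ss_distance initial S-S distance, A
#' @param angle initial C-S-S angles, degrees
#' @param dihedral initial C-S-S-C dihedral, degrees
#' @param seed seed for the dynamics RNG state
#' @return list with \code{topology} and \code{frame}
#' @export
four_bead_css_c <- function(ss_distance = 2.4, angle = 120, dihedral = 90,
                            seed = 1) {
  particles <- data.frame(name = c("CA", "SG", "SG", "CA"),
                          resid = c(1, 1, 2, 2),
                          mass = c(.bb_mass, .sg_mass, .sg_mass, .bb_mass))
  bonds <- data.frame(i = c(1, 3), j = c(2, 4), k = .sg_bond_k,
                      r0 = .sg_bond_r0)
  top <- cg_topology(particles = particles, bonds = bonds,
                     residue_labels = c("CYR", "CYR"),
                     reactive_sites = c(2, 3))
  top <- set_lj_mask(top, TRUE)
  th <- .deg2rad(angle)
  c1 <- c(0, 0, 0)
  s2 <- c(.sg_bond_r0, 0, 0)
  s3 <- s2 + ss_distance * c(cos(pi - th), sin(pi - th), 0)
  c4 <- .place_atom(s2, s3, c1, .sg_bond_r0, angle, dihedral)
  pos <- rbind(c1, s2, s3, c4)
  pos <- sweep(pos, 2, colMeans(pos))
  list(topology = top,
       frame = new_frame(0, pos, rng_state = seed_rng(seed)))
}

# Place atom D at bond length from C, with angle B-C-D and dihedral
# A-B-C-D (NeRF construction).
.place_atom <- function(b, c_, a, bond, angle, dihedral) {
  th <- .deg2rad(angle); ph <- .deg2rad(dihedral)
  bc <- c_ - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nrm <- .cross(ab, bc); nrm <- nrm / sqrt(sum(nrm^2))
  m <- .cross(nrm, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * nrm
}
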