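#' Harmonic restraints
#'
#' Artificial restraints used to install the disulfide geometry.  All are
#' harmonic in the Amber-style form without the 1/2 factor, scaled by the
#' ramp factor alpha: a distance restraint contributes
#' \eqn{\alpha k (r - r_0)^2}, angle and dihedral restraints
#' \eqn{\alpha k (\theta - \theta_0)^2} with the deviation in radians and,
#' for dihedrals, taken on the shortest arc.
#'
#' @param pair two particle indices
#' @param target target distance (A), angle or dihedral (degrees)
#' @param k force constant: kcal/mol/A^2 for distances, kcal/mol/rad^2 for
#'   angles and dihedrals
#' @return a \code{restraint_set} holding the single restraint
#' @export
distance_restraint <- function(pair, target = 2.038, k = 166) {
  stopifnot(target > 0, k > 0)
  restraint_set(distance = data.frame(i = min(pair), j = max(pair),
                                      k = k, r0 = target))
}

#' @rdname distance_restraint
#' @param triple three particle indices (i-j-k, angle at j)
#' @export
angle_restraint <- function(triple, target = 103.7, k = 68) {
  stopifnot(target > 0, target < 180, k > 0)
  restraint_set(angles = data.frame(i = triple[1], j = triple[2],
                                    k = triple[3], kf = k, theta0 = target))
}

#' @rdname distance_restraint
#' @param quad four particle indices (dihedral i-j-k-l)
#' @export
dihedral_restraint <- function(quad, target = 90, k = 3.5) {
  stopifnot(target > -180, target <= 180, k > 0)
  restraint_set(dihedrals = data.frame(i = quad[1], j = quad[2], k = quad[3],
                                       l = quad[4], kf = k, phi0 = target))
}

#' Combine restraints into a set
#'
#' @param distance,angles,dihedrals data frames in the column layout used by
#'   \code{\link{cg_topology}} bonded terms
#' @param ... further \code{restraint_set} objects to merge
#' @return an object of class \code{restraint_set}
#' @export
restraint_set <- function(distance = NULL, angles = NULL, dihedrals = NULL,
                          ...) {
  rs <- structure(list(
    distance = if (is.null(distance))
      data.frame(i = integer(), j = integer(), k = numeric(),
                 r0 = numeric()) else distance,
    angles = if (is.null(angles))
      data.frame(i = integer(), j = integer(), k = integer(), kf = numeric(),
                 theta0 = numeric()) else angles,
    dihedrals = if (is.null(dihedrals))
      data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
                 kf = numeric(), phi0 = numeric()) else dihedrals),
    class = "restraint_set")
  for (other in list(...)) rs <- merge_restraints(rs, other)
  rs
}

#' @rdname restraint_set
#' @param a,b restraint sets
#' @export
merge_restraints <- function(a, b) {
  structure(list(distance = rbind(a$distance, b$distance),
                 angles = rbind(a$angles, b$angles),
                 dihedrals = rbind(a$dihedrals, b$dihedrals)),
            class = "restraint_set")
}

#' Disulfide restraint set for a reactive pair
#'
#' The artificial restraints imitating the disulfide bond: built from the
#' same terms as the eventual permanent bond (see
#' \code{\link{disulfide_terms}}), so that at full ramp strength the
#' restraints and the generic bond are exactly equivalent.
#'
#' @param top a \code{cg_topology}
#' @param pair the two sulfur particle indices
#' @param terms bonded terms; defaults to \code{disulfide_terms(top, pair)}
#' @return a \code{restraint_set}
#' @export
disulfide_restraints <- function(top, pair,
                                 terms = disulfide_terms(top, pair)) {
  restraint_set(distance = terms$bonds,
                angles = setNames(terms$angles,
                                  c("i", "j", "k", "kf", "theta0")),
                dihedrals = terms$dihedrals)
}

#' Total restraint energy
#'
#' Sum over active restraints of \eqn{\alpha k (x - x_0)^2}, with angle and
#' dihedral deviations in radians and the dihedral deviation on the shortest
#' arc.
#'
#' @param positions n x 3 coordinate matrix (A) or a \code{cg_frame}
#' @param restraints a \code{restraint_set}
#' @param alpha restraint scale factor in [0, 1]
#' @return energy, kcal/mol
#' @export
restraint_energy <- function(positions, restraints, alpha = 1) {
  if (inherits(positions, "cg_frame")) positions <- positions$positions
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  n <- nrow(positions)
  idx <- c(restraints$distance$i, restraints$distance$j,
           restraints$angles$i, restraints$angles$j, restraints$angles$k,
           restraints$dihedrals$i, restraints$dihedrals$j,
           restraints$dihedrals$k, restraints$dihedrals$l)
  if (length(idx) && (any(idx < 1) || any(idx > n)))
    stop("topology error: restraint references particle out of range")
  e <- 0
  d <- restraints$distance
  if (nrow(d)) {
    r <- sqrt(rowSums((positions[d$i, , drop = FALSE] -
                         positions[d$j, , drop = FALSE])^2))
    e <- e + sum(d$k * (r - d$r0)^2)
  }
  a <- restraints$angles
  if (nrow(a)) {
    for (t in seq_len(nrow(a))) {
      th <- .angle_deg(positions, a$i[t], a$j[t], a$k[t])
      e <- e + a$kf[t] * (.deg2rad(th - a$theta0[t]))^2
    }
  }
  h <- restraints$dihedrals
  if (nrow(h)) {
    for (t in seq_len(nrow(h))) {
      ph <- .dihedral_deg(positions, h$i[t], h$j[t], h$k[t], h$l[t])
      dev <- .wrap180(ph - h$phi0[t])
      e <- e + h$kf[t] * (.deg2rad(dev))^2
    }
  }
  alpha * e
}

.angle_deg <- function(x, i, j, k) {
  u <- x[i, ] - x[j, ]; v <- x[k, ] - x[j, ]
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  .rad2deg(acos(pmin(1, pmax(-1, ct))))
}

.dihedral_deg <- function(x, i, j, k, l) {
  b1 <- x[j, ] - x[i, ]; b2 <- x[k, ] - x[j, ]; b3 <- x[l, ] - x[k, ]
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  .rad2deg(atan2(sum(.cross(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2)))
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.wrap180 <- function(d) ((d + 180) %% 360) - 180

#' @export
print.restraint_set <- function(x, ...) {
  cat("Restraint set:", nrow(x$distance), "distance,", nrow(x$angles),
      "angle,", nrow(x$dihedrals), "dihedral\n")
  invisible(x)
}
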