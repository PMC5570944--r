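#' Lennard-Jones pair-potential parameters
#'
#' Parameters of the pairwise potential
#' \eqn{\varepsilon ((r_0/r)^{12} - 2 (r_0/r)^6)}, truncated (not shifted)
#' at the cutoff.  Defaults are the sulfur-sulfur parameters of the
#' underlying all-atom parameterization: well depth 0.25 kcal/mol, minimum
#' at 4 A, 10.5 A cutoff.  \code{r0_shrunk} is the alternative equilibrium
#' distance (2 A) used for reactive pairs in \code{lj_mode = "shrunk_r0"},
#' where the reactive-pair potential is contracted instead of masked.
#'
#' @param epsilon well depth, kcal/mol (>= 0)
#' @param r0 minimum-energy distance, A
#' @param cutoff truncation distance, A (> r0)
#' @param r0_shrunk equilibrium distance used for reactive pairs in
#'   \code{shrunk_r0} mode, A
#' @return an object of class \code{lj_params}
#' @export
lj_params <- function(epsilon = 0.25, r0 = 4, cutoff = 10.5, r0_shrunk = 2) {
  stopifnot(epsilon >= 0, r0 > 0, r0 < cutoff, r0_shrunk > 0)
  structure(list(epsilon = epsilon, r0 = r0, cutoff = cutoff,
                 r0_shrunk = r0_shrunk), class = "lj_params")
}

.pair_mat <- function(pairs) {
  # normalize a pair container to a k x 2 matrix with i < j
  if (is.null(pairs) || length(pairs) == 0)
    return(matrix(integer(), 0, 2))
  if (is.matrix(pairs)) m <- pairs
  else if (is.list(pairs)) m <- do.call(rbind, lapply(pairs, as.integer))
  else m <- matrix(as.integer(pairs), ncol = 2, byrow = TRUE)
  t(apply(m, 1, function(p) sort(as.integer(p))))
}

.pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "-")

.pair_in <- function(pairs, i, j) {
  if (nrow(pairs) == 0) return(FALSE)
  any(pairs[, 1] == pmin(i, j) & pairs[, 2] == pmax(i, j))
}

# 1-2 and 1-3 exclusions from the bond graph (standard convention: bonded
# neighbors and next-nearest neighbors do not interact through LJ).
.exclusions_from_bonds <- function(bonds, n) {
  adj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (t in seq_len(nrow(bonds))) {
      i <- bonds$i[t]; j <- bonds$j[t]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  out <- list()
  for (i in seq_len(n)) {
    one <- adj[[i]]
    two <- unique(unlist(adj[one]))
    for (j in union(one, two)) {
      if (j > i) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  .pair_mat(out)
}

#' Construct a coarse-grained topology
#'
#' The coarse representation is one backbone bead per residue plus one sulfur
#' bead ("SG") bonded to each cysteine backbone bead.  Residue type codes:
#' a generic code (e.g. \code{"ALA"}) for ordinary residues, \code{"CYR"}
#' for a reactive (deprotonated, neutral) cysteine and \code{"CYX"} for a
#' disulfide-bonded cysteine.  The topology carries the reactive-site
#' registry, the current disulfide set, and the Lennard-Jones mask: the set
#' of sulfur-sulfur pairs whose pairwise LJ term is disabled so that they
#' can reach the capture radius.  The mask exists only between reactive
#' sulfurs and only while \code{mask_active} is \code{TRUE} (the reactive
#' folding stage).
#'
#' @param particles data frame with columns \code{name} (\code{"CA"} or
#'   \code{"SG"}), \code{resid} (1-based residue number) and \code{mass}
#'   (amu)
#' @param bonds data frame with columns \code{i}, \code{j} (particle
#'   indices), \code{k} (kcal/mol/A^2) and \code{r0} (A); energy
#'   \eqn{k (r - r_0)^2}
#' @param residue_labels character vector of residue type codes, one per
#'   residue
#' @param angles data frame with columns \code{i}, \code{j}, \code{k},
#'   \code{kf} (kcal/mol/rad^2), \code{theta0} (degrees)
#' @param dihedrals data frame with columns \code{i}, \code{j}, \code{k},
#'   \code{l}, \code{kf} (kcal/mol/rad^2), \code{phi0} (degrees)
#' @param reactive_sites particle indices (SG beads) currently reactive
#' @param lj \code{\link{lj_params}}
#' @param lj_mode \code{"masked"} (reactive-pair LJ switched off) or
#'   \code{"shrunk_r0"} (reactive-pair LJ minimum moved to
#'   \code{lj$r0_shrunk})
#' @param sphere_radius radius (A) of the reflective confining sphere
#'   centred at the origin; replaces periodic boundaries in vacuum
#' @return an object of class \code{cg_topology}
#' @export
cg_topology <- function(particles, bonds, residue_labels,
                        angles = NULL, dihedrals = NULL,
                        reactive_sites = integer(),
                        lj = lj_params(), lj_mode = c("masked", "shrunk_r0"),
                        sphere_radius = 60) {
  lj_mode <- match.arg(lj_mode)
  empty_angles <- data.frame(i = integer(), j = integer(), k = integer(),
                             kf = numeric(), theta0 = numeric())
  empty_dihedrals <- data.frame(i = integer(), j = integer(), k = integer(),
                                l = integer(), kf = numeric(),
                                phi0 = numeric())
  top <- structure(list(
    residue_labels = as.character(residue_labels),
    particles = particles,
    n_particles = nrow(particles),
    bonds = if (is.null(bonds)) data.frame(i = integer(), j = integer(),
                                           k = numeric(), r0 = numeric())
            else bonds,
    angles = if (is.null(angles)) empty_angles else angles,
    dihedrals = if (is.null(dihedrals)) empty_dihedrals else dihedrals,
    reactive_sites = sort(as.integer(reactive_sites)),
    disulfides = matrix(integer(), 0, 2),
    disulfide_terms = list(),
    lj = lj, lj_mode = lj_mode,
    mask_active = FALSE,
    lj_mask = matrix(integer(), 0, 2),
    exclusions = NULL,
    sphere_radius = sphere_radius,
    version = 1L), class = "cg_topology")
  top$exclusions <- .exclusions_from_bonds(top$bonds, top$n_particles)
  validate_topology(top)
  top
}

#' Validate topology invariants
#'
#' Checks that every masked pair has both members in the reactive-site
#' registry, that no disulfide-bonded particle is still reactive, that no
#' particle appears in more than one disulfide, and that all indices are in
#' range.
#'
#' @param top a \code{cg_topology}
#' @return \code{top}, invisibly; errors on violation
#' @export
validate_topology <- function(top) {
  n <- top$n_particles
  idx <- c(top$bonds$i, top$bonds$j, top$angles$i, top$angles$j, top$angles$k,
           top$dihedrals$i, top$dihedrals$j, top$dihedrals$k, top$dihedrals$l,
           top$reactive_sites, as.integer(top$disulfides))
  if (length(idx) && (any(idx < 1) || any(idx > n)))
    stop("topology error: particle index out of range [1, ", n, "]")
  if (nrow(top$lj_mask) > 0 &&
      !all(as.integer(top$lj_mask) %in% top$reactive_sites))
    stop("topology error: lj_mask pair outside the reactive set")
  if (nrow(top$disulfides) > 0) {
    ss <- as.integer(top$disulfides)
    if (any(ss %in% top$reactive_sites))
      stop("topology error: disulfide-bonded particle still reactive")
    if (anyDuplicated(ss))
      stop("topology error: particle in more than one disulfide")
  }
  if (!identical(nrow(top$particles), n))
    stop("topology error: particle table size mismatch")
  invisible(top)
}

#' Activate or deactivate the reactive Lennard-Jones mask
#'
#' With the mask active (the reactive folding stage), every pair of reactive
#' sulfurs has its LJ term disabled (\code{lj_mode = "masked"}) or contracted
#' to \code{r0_shrunk} (\code{lj_mode = "shrunk_r0"}).  With the mask
#' inactive the potential is the standard, unaltered one.
#'
#' @param top a \code{cg_topology}
#' @param active logical
#' @return the updated topology
#' @export
set_lj_mask <- function(top, active) {
  top$mask_active <- isTRUE(active)
  top$lj_mask <- if (top$mask_active && top$lj_mode == "masked" &&
                     length(top$reactive_sites) >= 2)
    .pair_mat(t(combn(top$reactive_sites, 2)))
  else matrix(integer(), 0, 2)
  top$version <- top$version + 1L
  validate_topology(top)
  top
}

#' All currently reactive sulfur pairs
#'
#' @param top a \code{cg_topology}
#' @return a k x 2 matrix of particle index pairs (i < j)
#' @export
reactive_pairs <- function(top) {
  if (length(top$reactive_sites) < 2) return(matrix(integer(), 0, 2))
  .pair_mat(t(combn(top$reactive_sites, 2)))
}

# Backbone (CA) bead bonded to an SG bead, or NA.
.sg_host <- function(top, sg) {
  b <- top$bonds
  hit <- c(b$j[b$i == sg], b$i[b$j == sg])
  hit <- hit[top$particles$name[hit] == "CA"]
  if (length(hit)) hit[1] else NA_integer_
}

#' Bonded terms describing a disulfide bridge
#'
#' Builds the permanent bond/angle/dihedral terms for a disulfide between two
#' sulfur beads: the S-S bond (k = 166 kcal/mol/A^2, r0 = 2.038 A), the two
#' C-S-S / S-S-C angles (target 103.7 degrees), and a single C-S-S-C dihedral
#' restrained harmonically at +/-90 degrees.  Angle/dihedral terms are only
#' generated where the corresponding backbone beads exist, so the two-bead
#' fixture yields a distance term only.  The same terms, scaled by the ramp
#' factor alpha, serve as the artificial restraints during bond formation,
#' which makes the final restraints and the installed generic bond exactly
#' equivalent.
#'
#' @param top a \code{cg_topology}
#' @param pair the two sulfur particle indices
#' @param bond_k,bond_r0 S-S force constant (kcal/mol/A^2) and target (A)
#' @param angle_k,angle_theta0 angle force constant (kcal/mol/rad^2) and
#'   target (degrees)
#' @param dihedral_k,dihedral_phi0 dihedral force constant (kcal/mol/rad^2)
#'   and target (degrees); the sign of the default +/-90 target is usually
#'   chosen from the geometry at ramp entry
#' @return list with data frames \code{bonds}, \code{angles},
#'   \code{dihedrals}
#' @export
disulfide_terms <- function(top, pair, bond_k = 166, bond_r0 = 2.038,
                            angle_k = 68, angle_theta0 = 103.7,
                            dihedral_k = 3.5, dihedral_phi0 = 90) {
  a <- min(pair); b <- max(pair)
  ca <- .sg_host(top, a); cb <- .sg_host(top, b)
  bonds <- data.frame(i = a, j = b, k = bond_k, r0 = bond_r0)
  angles <- data.frame(i = integer(), j = integer(), k = integer(),
                       kf = numeric(), theta0 = numeric())
  if (!is.na(ca))
    angles <- rbind(angles, data.frame(i = ca, j = a, k = b, kf = angle_k,
                                       theta0 = angle_theta0))
  if (!is.na(cb))
    angles <- rbind(angles, data.frame(i = a, j = b, k = cb, kf = angle_k,
                                       theta0 = angle_theta0))
  dihedrals <- data.frame(i = integer(), j = integer(), k = integer(),
                          l = integer(), kf = numeric(), phi0 = numeric())
  if (!is.na(ca) && !is.na(cb))
    dihedrals <- data.frame(i = ca, j = a, k = b, l = cb, kf = dihedral_k,
                            phi0 = dihedral_phi0)
  list(bonds = bonds, angles = angles, dihedrals = dihedrals)
}

#' Convert a captured reactive pair into a permanent disulfide
#'
#' The pair is added to the disulfide set, both sulfurs are removed from the
#' reactive-site registry (their residues are relabelled from CYR to CYX),
#' every LJ-mask entry involving them is removed so all their LJ interactions
#' return to normal, and permanent bond/angle/dihedral terms with full force
#' constants are installed.  The new S-S bond enters the bond graph, so the
#' 1-2/1-3 exclusions are recomputed; the newly excluded pairs are exactly
#' the ones masked during the preceding restraint ramp, which makes the
#' replacement of the fully ramped restraints by the generic bond
#' energy-neutral.
#'
#' @param top a \code{cg_topology}
#' @param pair the two sulfur particle indices (must both be reactive)
#' @param terms bonded terms as returned by \code{\link{disulfide_terms}};
#'   pass the terms used during the ramp so targets agree
#' @return the mutated topology
#' @export
form_disulfide <- function(top, pair, terms = disulfide_terms(top, pair)) {
  a <- min(pair); b <- max(pair)
  if (!all(c(a, b) %in% top$reactive_sites))
    stop("logic error: pair (", a, ",", b, ") is not reactive ",
         "(already bonded or never a reactive site)")
  top$disulfides <- rbind(top$disulfides, c(a, b))
  top$reactive_sites <- setdiff(top$reactive_sites, c(a, b))
  for (p in c(a, b)) {
    res <- top$particles$resid[p]
    if (top$residue_labels[res] == "CYR") top$residue_labels[res] <- "CYX"
  }
  top$bonds <- rbind(top$bonds, terms$bonds)
  top$angles <- rbind(top$angles, terms$angles)
  top$dihedrals <- rbind(top$dihedrals, terms$dihedrals)
  top$disulfide_terms[[.pair_key(a, b)]] <- terms
  top$exclusions <- .exclusions_from_bonds(top$bonds, top$n_particles)
  top <- set_lj_mask(top, top$mask_active) # drops mask entries of a and b
  top
}

#' Reverse a disulfide bond (reduction)
#'
#' Undoes \code{\link{form_disulfide}}: removes the bonded terms installed
#' for the pair, restores both sulfurs to the reactive registry (CYX back to
#' CYR) and rebuilds the LJ mask and exclusions.
#'
#' @param top a \code{cg_topology}
#' @param pair the two sulfur particle indices of an existing disulfide
#' @return the mutated topology
#' @export
reduce_disulfide <- function(top, pair) {
  a <- min(pair); b <- max(pair)
  key <- .pair_key(a, b)
  if (!.pair_in(top$disulfides, a, b))
    stop("no disulfide between particles ", a, " and ", b)
  terms <- top$disulfide_terms[[key]]
  keep <- !(top$disulfides[, 1] == a & top$disulfides[, 2] == b)
  top$disulfides <- top$disulfides[keep, , drop = FALSE]
  top$disulfide_terms[[key]] <- NULL
  # remove one matching row per installed term
  for (what in c("bonds", "angles", "dihedrals")) {
    sub <- terms[[what]]
    if (is.null(sub) || nrow(sub) == 0) next
    df <- top[[what]]
    for (t in seq_len(nrow(sub))) {
      keyed <- do.call(paste, c(df, sep = "|"))
      target <- paste(sub[t, ], collapse = "|")
      hit <- which(keyed == target)[1]
      if (!is.na(hit)) df <- df[-hit, , drop = FALSE]
    }
    top[[what]] <- df
  }
  top$reactive_sites <- sort(c(top$reactive_sites, a, b))
  for (p in c(a, b)) {
    res <- top$particles$resid[p]
    if (top$residue_labels[res] == "CYX") top$residue_labels[res] <- "CYR"
  }
  top$exclusions <- .exclusions_from_bonds(top$bonds, top$n_particles)
  top <- set_lj_mask(top, top$mask_active)
  top
}

# Pairs that would become 1-2/1-3 exclusions if `pair` were bonded, minus the
# current exclusions.  Masked from LJ while the bond-forming ramp is active.
.prospective_exclusions <- function(top, pair) {
  with_bond <- rbind(top$bonds,
                     data.frame(i = min(pair), j = max(pair), k = 0, r0 = 1))
  new <- .exclusions_from_bonds(with_bond, top$n_particles)
  old_keys <- .pair_key(top$exclusions[, 1], top$exclusions[, 2])
  keep <- !(.pair_key(new[, 1], new[, 2]) %in% old_keys)
  new[keep, , drop = FALSE]
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("Coarse-grained topology:", x$n_particles, "particles,",
      length(x$residue_labels), "residues\n")
  cat("  bonds:", nrow(x$bonds), " angles:", nrow(x$angles),
      " dihedrals:", nrow(x$dihedrals), "\n")
  cat("  reactive sites:",
      if (length(x$reactive_sites)) paste(x$reactive_sites, collapse = ", ")
      else "none", "\n")
  cat("  disulfides:",
      if (nrow(x$disulfides))
        paste(apply(x$disulfides, 1, paste, collapse = "-"), collapse = ", ")
      else "none", "\n")
  cat("  LJ mask:", if (x$mask_active) paste0("active (", nrow(x$lj_mask),
                                              " pairs, mode ", x$lj_mode, ")")
      else "inactive", "\n")
  invisible(x)
}
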