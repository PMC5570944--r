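# Trajectory and ensemble statistics: isomer bookkeeping, kinetic
# footprints, radius of gyration, ensemble RMSD, NOE violations.

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the selected particles from
#' their centre of mass.
#'
#' @param frame a \code{cg_frame} or n x 3 coordinate matrix
#' @param selection particle indices (default: all)
#' @param masses particle masses, amu (default: unit masses)
#' @return radius of gyration, A
#' @export
radius_of_gyration <- function(frame, selection = NULL, masses = NULL) {
  x <- if (inherits(frame, "cg_frame")) frame$positions else as.matrix(frame)
  if (is.null(selection)) selection <- seq_len(nrow(x))
  if (length(selection) == 0) stop("empty selection")
  x <- x[selection, , drop = FALSE]
  m <- if (is.null(masses)) rep(1, nrow(x)) else masses[selection]
  com <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums((x - rep(com, each = nrow(x)))^2)) / sum(m))
}

#' Enumerate complete disulfide pairings
#'
#' All perfect matchings of an even set of cysteine positions; each position
#' is used exactly once.  For n positions there are (n-1)!! matchings; the
#' four cysteines of guanylin admit exactly three, one per isomer.
#'
#' @param cys_positions even-length vector of cysteine residue positions
#' @return list of pairings, each a list of sorted position pairs
#' @export
enumerate_pairings <- function(cys_positions) {
  pos <- sort(unique(as.integer(cys_positions)))
  if (length(pos) != length(cys_positions))
    stop("cysteine positions must be distinct")
  if (length(pos) %% 2 != 0)
    stop("odd number of cysteine positions cannot be fully paired")
  if (length(pos) == 0) return(list(list()))
  first <- pos[1]
  out <- list()
  for (partner in pos[-1]) {
    rest <- setdiff(pos, c(first, partner))
    for (sub in enumerate_pairings(rest))
      out[[length(out) + 1L]] <- c(list(c(first, partner)), sub)
  }
  out
}

#' Classify a disulfide pattern into a guanylin isomer
#'
#' For cysteines at positions (4, 7, 12, 15): pairing
#' \{(4,7), (12,15)\} is isomer 1, \{(4,12), (7,15)\} is isomer 2 (the
#' biologically active form), \{(4,15), (7,12)\} is isomer 3.  A single
#' bond yields \code{"partial"} together with the unique complete pairing
#' it commits to (always unique with four cysteines); an empty set yields
#' \code{"none"}.
#'
#' @param disulfides set of residue-position pairs (list of length-2
#'   vectors, or a k x 2 matrix)
#' @param cys_positions the cysteine positions (default guanylin's)
#' @return list with \code{label} (\code{"isomer1"}, \code{"isomer2"},
#'   \code{"isomer3"}, \code{"partial"} or \code{"none"}),
#'   \code{pairing} (the complete pairing, or the partial set) and, for
#'   partial patterns, \code{committed_to}
#' @export
classify_isomer <- function(disulfides, cys_positions = c(4, 7, 12, 15)) {
  pairs <- if (is.matrix(disulfides))
    lapply(seq_len(nrow(disulfides)), function(t) sort(disulfides[t, ]))
  else lapply(disulfides, sort)
  used <- unlist(pairs)
  if (anyDuplicated(used))
    stop("invalid pairing: a cysteine appears in more than one disulfide")
  if (length(used) && !all(used %in% cys_positions))
    stop("invalid pairing: position outside the cysteine set")
  canon <- enumerate_pairings(cys_positions)
  key <- function(p) paste(vapply(p[order(vapply(p, `[`, 1, 1))],
                                  paste, "", collapse = "-"),
                           collapse = ",")
  labels <- paste0("isomer", seq_along(canon))
  names(labels) <- vapply(canon, key, "")
  if (length(pairs) == 0)
    return(list(label = "none", pairing = list()))
  if (length(used) == length(cys_positions)) {
    lab <- unname(labels[key(pairs)])
    if (is.na(lab)) stop("invalid pairing")
    return(list(label = lab, pairing = pairs))
  }
  # partial: find the complete pairings extending the committed bonds
  have <- vapply(pairs, paste, "", collapse = "-")
  ext <- Filter(function(p)
    all(have %in% vapply(p, paste, "", collapse = "-")), canon)
  list(label = "partial", pairing = pairs,
       committed_to = if (length(ext) == 1) labels[[key(ext[[1]])]]
                      else NA_character_)
}

#' Kinetic footprint of an ensemble of folding runs
#'
#' One row per trajectory: time of the first and second disulfide formation
#' (ps, on the folding-stage clock) and the isomer the run produced or
#' committed to.  The summary attribute reports mean first/second bond
#' times and isomer fractions.
#'
#' @param runs list of \code{redox_run} objects, or list of event data
#'   frames (then \code{fold_start} gives each run's folding-stage start
#'   time)
#' @param fold_start numeric vector of folding-stage start times for plain
#'   event logs (recycled)
#' @return data frame with columns \code{trajectory}, \code{t_first},
#'   \code{t_second}, \code{isomer}; summary list in
#'   \code{attr(, "summary")}
#' @export
kinetic_footprint <- function(runs, fold_start = 0) {
  fold_start <- rep_len(fold_start, length(runs))
  rows <- lapply(seq_along(runs), function(t) {
    r <- runs[[t]]
    ev <- if (inherits(r, "redox_run")) r$events else r
    start <- if (inherits(r, "redox_run"))
      r$stage_boundaries[["folding"]] else fold_start[t]
    formed <- ev[ev$kind == "formed", , drop = FALSE]
    ss <- lapply(seq_len(nrow(formed)), function(q)
      sort(c(formed$res_i[q], formed$res_j[q])))
    # reduction events cancel the matching formed bond for labelling
    red <- ev[ev$kind == "reduced", , drop = FALSE]
    for (q in seq_len(nrow(red))) {
      k <- match(list(sort(c(red$res_i[q], red$res_j[q]))), ss)
      if (!is.na(k)) ss <- ss[-k]
    }
    iso <- classify_isomer(ss)
    lab <- if (iso$label == "partial") "partial" else iso$label
    data.frame(trajectory = t,
               t_first = if (nrow(formed) >= 1) formed$time[1] - start
                         else NA_real_,
               t_second = if (nrow(formed) >= 2) formed$time[2] - start
                          else NA_real_,
               isomer = lab)
  })
  out <- do.call(rbind, rows)
  complete <- out$isomer[grepl("^isomer", out$isomer)]
  attr(out, "summary") <- list(
    mean_t_first = mean(out$t_first, na.rm = TRUE),
    mean_t_second = mean(out$t_second, na.rm = TRUE),
    isomer_fractions = if (length(complete))
      table(complete) / length(complete) else table(character()))
  out
}

# --- rigid-body superposition (Kabsch, via SVD) ----------------------------

#' Optimal rigid-body superposition
#'
#' Least-squares superposition (rotation + translation, no scaling) of
#' \code{mobile} onto \code{target} and the residual RMSD.
#'
#' @param mobile,target n x 3 coordinate matrices
#' @return list with \code{coords} (superposed mobile), \code{rmsd},
#'   \code{rotation}, \code{translation}
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)))
    stop("mismatched atom counts in superposition")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P %*% t(R)
  list(coords = sweep(fitted, 2, ct, "+"),
       rmsd = sqrt(mean(rowSums((fitted - Q)^2))),
       rotation = R, translation = ct - as.vector(R %*% cm))
}

#' Ensemble RMSD and pairwise RMSD matrix
#'
#' Each conformer is superposed (optimal rotation + translation) before any
#' comparison.  The ensemble RMSD is the RMS deviation of the conformers
#' from their iteratively superposed mean structure: all conformers are
#' fitted to a reference, the mean is recomputed and used as the new
#' reference until convergence.  The pairwise matrix holds the RMSD of
#' every conformer pair after direct pairwise superposition; the smallest
#' cross-ensemble entry of such a matrix is the "lowest pairwise RMSD"
#' statistic.
#'
#' @param conformers list of \code{cg_frame} objects or n x 3 matrices with
#'   equal atom counts
#' @param selection optional atom indices used for the fit
#' @param tol convergence tolerance on the mean structure, A
#' @return list with \code{ensemble_rmsd} (A), \code{pairwise} (symmetric
#'   matrix, A), \code{mean_structure}, \code{per_conformer} (RMSD of each
#'   conformer to the mean)
#' @export
ensemble_rmsd <- function(conformers, selection = NULL, tol = 1e-10) {
  coords <- lapply(conformers, function(f)
    if (inherits(f, "cg_frame")) f$positions else as.matrix(f))
  if (length(coords) < 2) stop("need at least 2 conformers")
  nat <- vapply(coords, nrow, integer(1))
  if (length(unique(nat)) != 1) stop("mismatched atom counts")
  if (!is.null(selection))
    coords <- lapply(coords, function(x) x[selection, , drop = FALSE])
  ref <- coords[[1]]
  for (iter in 1:100) {
    fitted <- lapply(coords, function(x) superpose(x, ref)$coords)
    newref <- Reduce(`+`, fitted) / length(fitted)
    if (sqrt(mean((newref - ref)^2)) < tol) { ref <- newref; break }
    ref <- newref
  }
  per <- vapply(fitted, function(x) sqrt(mean(rowSums((x - ref)^2))),
                numeric(1))
  k <- length(coords)
  pw <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    pw[i, j] <- pw[j, i] <- superpose(coords[[i]], coords[[j]])$rmsd
  list(ensemble_rmsd = sqrt(mean(per^2)), pairwise = pw,
       mean_structure = ref, per_conformer = per)
}

# --- NOE violations --------------------------------------------------------

#' NOE restraint list
#'
#' A single NOE distance restraint: two atom groups (more than one selector
#' per group encodes unresolved/equivalent protons) and lower/upper distance
#' bounds in A.
#'
#' @param group_a,group_b character vectors of atom selectors
#'   (\code{"residue:atom"}, \code{*} wildcard allowed in the atom part)
#' @param r_low,r_high bounds, A (0 < r_low <= r_high)
#' @return a one-row \code{noe_restraint} list
#' @export
noe_restraint <- function(group_a, group_b, r_low, r_high) {
  if (!(r_low > 0 && r_low <= r_high))
    stop("NOE bounds must satisfy 0 < r_low <= r_high")
  structure(list(group_a = as.character(group_a),
                 group_b = as.character(group_b),
                 r_low = r_low, r_high = r_high), class = "noe_restraint")
}

.resolve_selector <- function(sel, atom_ids) {
  hits <- unique(unlist(lapply(sel, function(s)
    grep(utils::glob2rx(s), atom_ids))))
  if (!length(hits))
    stop("unresolvable NOE selector: ", paste(sel, collapse = ", "))
  hits
}

#' NOE violation score
#'
#' For each restraint the effective distance between the two groups is the
#' r^-6 sum over all inter-group atom pairs,
#' \eqn{r = (\sum_i r_i^{-6})^{-1/6}} (the standard treatment of
#' equivalent/unresolved protons).  The deviation is zero if the effective
#' distance is within the bounds, \eqn{r - r_{high}} above the upper bound
#' and \eqn{r_{low} - r} below the lower bound.  Deviations are combined
#' linearly and normalized by the number of restraints, giving the distance
#' violation per single NOE restraint.
#'
#' @param coords n x 3 coordinate matrix whose rownames are atom
#'   identifiers \code{"residue:atom"} (e.g. \code{"12:SG"}), or a
#'   \code{cg_frame} plus \code{topology}
#' @param restraints list of \code{\link{noe_restraint}} objects (e.g. from
#'   \code{\link{read_noe_table}})
#' @param topology optional \code{cg_topology} used to name the coordinates
#'   when \code{coords} is a frame
#' @return list with \code{deviations} (per restraint, A) and \code{mean}
#'   (A)
#' @export
noe_violation <- function(coords, restraints, topology = NULL) {
  if (inherits(coords, "cg_frame")) {
    if (is.null(topology))
      stop("supply the topology to resolve atom names for a frame")
    x <- coords$positions
    rownames(x) <- paste0(topology$particles$resid, ":",
                          topology$particles$name)
    coords <- x
  }
  coords <- as.matrix(coords)
  ids <- rownames(coords)
  if (is.null(ids)) stop("coordinates must carry 'residue:atom' rownames")
  if (inherits(restraints, "noe_restraint")) restraints <- list(restraints)
  dev <- vapply(restraints, function(rr) {
    ia <- .resolve_selector(rr$group_a, ids)
    ib <- .resolve_selector(rr$group_b, ids)
    r6 <- 0
    for (a in ia) for (b in ib) {
      d2 <- sum((coords[a, ] - coords[b, ])^2)
      r6 <- r6 + d2^(-3)
    }
    reff <- r6^(-1 / 6)
    if (reff > rr$r_high) reff - rr$r_high
    else if (reff < rr$r_low) rr$r_low - reff
    else 0
  }, numeric(1))
  list(deviations = dev, mean = if (length(dev)) mean(dev) else 0)
}

#' Per-pair sulfur-sulfur distance series
#'
#' One distance series per reactive or bonded sulfur pair, evaluated on
#' every stored frame; input for contact-lifetime statistics.  The series
#' is symmetric in the pair by construction.
#'
#' @param frames list of \code{cg_frame} objects (or a \code{redox_run})
#' @param top a \code{cg_topology}
#' @param pairs optional k x 2 matrix of particle pairs; defaults to all
#'   reactive-or-bonded sulfur pairs
#' @return matrix (frames x pairs) of distances, A, with \code{"resI-resJ"}
#'   column names and times as rownames
#' @export
ss_distance_series <- function(frames, top, pairs = NULL) {
  if (inherits(frames, "redox_run")) frames <- frames$frames
  if (is.null(pairs)) {
    sg <- sort(unique(c(top$reactive_sites, as.integer(top$disulfides))))
    if (length(sg) < 2) return(matrix(numeric(), length(frames), 0))
    pairs <- .pair_mat(t(combn(sg, 2)))
  } else pairs <- .pair_mat(pairs)
  d <- t(vapply(frames, function(f)
    sqrt(rowSums((f$positions[pairs[, 1], , drop = FALSE] -
                    f$positions[pairs[, 2], , drop = FALSE])^2)),
    numeric(nrow(pairs))))
  if (nrow(pairs) == 1) d <- matrix(d, ncol = 1)
  colnames(d) <- paste0(top$particles$resid[pairs[, 1]], "-",
                        top$particles$resid[pairs[, 2]])
  rownames(d) <- vapply(frames, function(f) format(f$time), "")
  d
}

#' Inscribed-sphere diameter of a truncated octahedron
#'
#' For a truncated-octahedron simulation cell with edge length l the
#' diameter of the inscribed sphere equals the unit-cell parameter:
#' \eqn{d = a = l \sqrt{6}}.
#'
#' @param edge_length edge length l, A (> 0)
#' @return diameter, A
#' @export
truncated_octahedron_diameter <- function(edge_length) {
  if (any(edge_length <= 0)) stop("edge length must be positive")
  edge_length * sqrt(6)
}
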