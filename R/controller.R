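# The reactive oxidative-folding controller: segmented simulation, capture
# detection on stored frames, stochastic reactivity gating, bitwise rewind to
# the crossing frame, restraint ramping, topology mutation, optional
# reduction.

#' Detect the first capture in a segment
#'
#' Scans the stored frames of a segment in time order and returns the
#' earliest frame at which any reactive sulfur pair is within the capture
#' radius.  Ties within one frame are broken by smallest distance, then by
#' lexicographically smallest pair, so detection is deterministic.
#'
#' @param segment a \code{cg_segment}
#' @param top a \code{cg_topology} (supplies the reactive pairs)
#' @param r_c capture radius, A
#' @return \code{NULL} if no pair crosses, else a list with
#'   \code{frame_index}, \code{pair} (particle indices) and \code{distance}
#' @export
detect_capture <- function(segment, top, r_c = 2.5) {
  pairs <- reactive_pairs(top)
  if (nrow(pairs) == 0) return(NULL)
  for (f in seq_along(segment$frames)) {
    hit <- .frame_contacts(segment$frames[[f]], pairs, r_c)
    if (!is.null(hit))
      return(list(frame_index = f, pair = hit$pair[1, ],
                  distance = hit$distance[1]))
  }
  NULL
}

# All contact pairs in one frame, sorted by (distance, pair): NULL or a list
# with matrix `pair` and vector `distance`.
.frame_contacts <- function(frame, pairs, r_c) {
  d <- sqrt(rowSums((frame$positions[pairs[, 1], , drop = FALSE] -
                       frame$positions[pairs[, 2], , drop = FALSE])^2))
  sel <- which(d <= r_c)
  if (!length(sel)) return(NULL)
  ord <- sel[order(d[sel], pairs[sel, 1], pairs[sel, 2])]
  list(pair = pairs[ord, , drop = FALSE], distance = d[ord])
}

#' Stochastic reactivity gate
#'
#' One Bernoulli decision per stored contact frame: a uniform draw on (0, 1)
#' is accepted iff it falls below \code{accept_prob}.  With
#' \code{accept_prob = 1} every thiol encounter is productive (the original
#' protocol); the reduced-reactivity protocol uses 0.001.  Uses R's RNG, so
#' seed with \code{set.seed()} for reproducibility.
#'
#' @param accept_prob acceptance probability in (0, 1]
#' @param n number of decisions to draw
#' @return logical vector of length \code{n}
#' @export
gate_decision <- function(accept_prob, n = 1) {
  if (!(accept_prob > 0 && accept_prob <= 1))
    stop("config error: accept_prob must be in (0, 1]")
  runif(n) < accept_prob
}

#' Replay a segment up to the crossing frame
#'
#' Re-propagates the segment from its stored start frame (restart point) for
#' exactly \code{n} frames and verifies that the replay reproduces the
#' stored frame bitwise, reproducing the state of the system at the precise
#' moment the capture radius was crossed.  Any divergence is a fatal
#' reproducibility error.
#'
#' @param segment a \code{cg_segment}
#' @param n frame index within the segment (1-based)
#' @param top the \code{cg_topology} the segment was propagated with
#' @return the \code{cg_frame} at frame \code{n}, bitwise identical to
#'   \code{segment$frames[[n]]}
#' @export
rewind_to_crossing <- function(segment, n, top) {
  if (is.null(n) || length(n) != 1 || is.na(n) || n < 1 ||
      n > length(segment$frames))
    stop("frame index must address a stored frame of the segment")
  ea <- segment$engine_args
  re <- run_segment(segment$start_frame, top,
                    length_ps = n * ea$frame_interval,
                    frame_interval = ea$frame_interval, dt = ea$dt,
                    gamma = ea$gamma, temperature = ea$temperature,
                    restraints = ea$restraints, alpha = ea$alpha,
                    extra_mask = ea$extra_mask)
  got <- re$frames[[n]]
  want <- segment$frames[[n]]
  if (!identical(got$positions, want$positions) ||
      !identical(got$velocities, want$velocities) ||
      !identical(got$rng_state, want$rng_state))
    stop("fatal reproducibility error: segment replay diverged at frame ", n)
  got
}

#' Ramp the disulfide restraints to full strength
#'
#' Propagates \code{n_steps} windows of \code{step_duration} ps with the
#' artificial disulfide restraints held at alpha = k / n_steps within window
#' k (k = 1..n_steps), gently pulling the sulfurs to the 2.038-A bond
#' length and steering the flanking angles toward 103.7 degrees.  While the
#' ramp is active the prospective bonded neighbourhood of the pair is masked
#' from LJ (it becomes the bond's 1-2/1-3 exclusions on installation), and
#' other reactive pairs stay masked but cannot trigger a new capture.
#'
#' @param state the \code{cg_frame} at the crossing (pair distance at or
#'   below the capture radius)
#' @param top a \code{cg_topology}
#' @param pair the captured sulfur pair
#' @param schedule a \code{\link{ramp_schedule}}
#' @param config a \code{\link{controller_config}} (supplies dt, gamma,
#'   temperature, frame_interval, capture radius)
#' @param terms bonded terms to install; the default picks the dihedral
#'   target sign (+90 or -90 degrees) from the geometry at entry
#' @return list with \code{frame} (final state), \code{frames} (all stored
#'   frames), \code{alphas} (per-window scale series), \code{terms}, and
#'   \code{window_distance} (per-window mean S-S distance, A)
#' @export
run_ramp <- function(state, top, pair, schedule = ramp_schedule(),
                     config = controller_config(), terms = NULL) {
  pair <- sort(pair)
  if (!all(pair %in% top$reactive_sites))
    stop("ramp requires a reactive pair")
  d0 <- sqrt(sum((state$positions[pair[1], ] -
                    state$positions[pair[2], ])^2))
  if (d0 > config$capture_radius + 1e-9)
    stop("ramp entered with pair distance ", signif(d0, 4),
         " A above the capture radius")
  if (is.null(terms)) {
    terms <- disulfide_terms(top, pair)
    if (nrow(terms$dihedrals)) { # pick the nearer of the +/-90 deg targets
      h <- terms$dihedrals
      phi <- .dihedral_deg(state$positions, h$i[1], h$j[1], h$k[1], h$l[1])
      terms$dihedrals$phi0 <- sign(ifelse(phi == 0, 1, phi)) *
        abs(terms$dihedrals$phi0)
    }
  }
  restraints <- disulfide_restraints(top, pair, terms)
  extra_mask <- .prospective_exclusions(top, pair)
  frames <- list()
  alphas <- numeric(schedule$n_steps)
  wmean <- numeric(schedule$n_steps)
  frame <- state
  dev_prev <- NULL; n_worse <- 0L
  for (k in seq_len(schedule$n_steps)) {
    alpha <- ramp_scale(schedule, k)
    seg <- run_segment(frame, top, length_ps = schedule$step_duration,
                       frame_interval = config$frame_interval,
                       dt = config$dt, gamma = config$gamma,
                       temperature = config$temperature,
                       restraints = restraints, alpha = alpha,
                       extra_mask = extra_mask)
    frame <- seg$frames[[length(seg$frames)]]
    frames <- c(frames, seg$frames)
    alphas[k] <- alpha
    d <- vapply(seg$frames, function(fr)
      sqrt(sum((fr$positions[pair[1], ] - fr$positions[pair[2], ])^2)),
      numeric(1))
    wmean[k] <- mean(d)
    dev <- abs(wmean[k] - terms$bonds$r0[1])
    if (!is.null(dev_prev) && dev > dev_prev) n_worse <- n_worse + 1L
    else n_worse <- 0L
    if (n_worse >= 3L && dev > 1.0)
      stop("ramp-failure: S-S distance diverging from target over 3 ",
           "consecutive windows (window ", k, ", mean ",
           signif(wmean[k], 4), " A)")
    dev_prev <- dev
  }
  list(frame = frame, frames = frames, alphas = alphas, terms = terms,
       window_distance = wmean)
}

#' Stochastic reduction of existing disulfides
#'
#' Optional reverse step of the protocol: each existing disulfide is reduced
#' with probability \code{base_prob * exposure(pair)} per decision, where
#' the exposure proxy mimics accessibility of the bridge to a reducing
#' agent.  A reduction restores both sulfurs to the reactive registry and
#' removes the bonded terms, and is reported as an event of kind
#' \code{"reduced"}.
#'
#' @param top a \code{cg_topology}
#' @param frame current \code{cg_frame} (for the exposure proxy)
#' @param config a \code{\link{reduction_config}}
#' @return list with the (possibly mutated) \code{topology} and a data frame
#'   of \code{events}
#' @export
maybe_reduce <- function(top, frame, config) {
  events <- .empty_events()
  if (!config$enabled || nrow(top$disulfides) == 0)
    return(list(topology = top, events = events))
  for (t in rev(seq_len(nrow(top$disulfides)))) {
    pair <- top$disulfides[t, ]
    p <- config$base_prob * .exposure(config$exposure_fn, top, frame, pair)
    if (runif(1) < p) {
      d <- sqrt(sum((frame$positions[pair[1], ] -
                       frame$positions[pair[2], ])^2))
      top <- reduce_disulfide(top, pair)
      events <- rbind(events, .event_row(frame, pair, top, d, 0L, "reduced"))
    }
  }
  list(topology = top, events = events)
}

.empty_events <- function() {
  data.frame(time = numeric(), frame = integer(), particle_i = integer(),
             particle_j = integer(), res_i = integer(), res_j = integer(),
             distance = numeric(), gate_draws = integer(),
             kind = character())
}

.event_row <- function(frame, pair, top, distance, gate_draws, kind,
                       frame_index = NA_integer_) {
  data.frame(time = frame$time, frame = as.integer(frame_index),
             particle_i = pair[1], particle_j = pair[2],
             res_i = top$particles$resid[pair[1]],
             res_j = top$particles$resid[pair[2]],
             distance = distance, gate_draws = as.integer(gate_draws),
             kind = kind)
}

# Scan a segment's frames; per contact frame make one gate decision per
# contact pair (closest first).  Returns NULL or the accepted capture.
.scan_segment <- function(segment, top, config, draws0 = 0L) {
  pairs <- reactive_pairs(top)
  draws <- draws0
  if (nrow(pairs) == 0) return(list(accepted = NULL, draws = draws))
  for (f in seq_along(segment$frames)) {
    hit <- .frame_contacts(segment$frames[[f]], pairs, config$capture_radius)
    if (is.null(hit)) next
    for (t in seq_len(nrow(hit$pair))) {
      ok <- gate_decision(config$accept_prob, 1)
      if (ok)
        return(list(accepted = list(frame_index = f, pair = hit$pair[t, ],
                                    distance = hit$distance[t],
                                    gate_draws = draws),
                    draws = draws))
      draws <- draws + 1L
    }
  }
  list(accepted = NULL, draws = draws)
}

#' Run the three-stage oxidative-folding protocol
#'
#' Stage 1 (equilibration) propagates the chain under the standard
#' potential: the reactive-pair LJ mask is inactive.  Stage 2 (oxidative
#' folding) activates the mask and repeats the segment loop: record a
#' restart point, propagate one segment, scan its stored frames for the
#' first sulfur-sulfur approach within the capture radius, pass each contact
#' frame through the reactivity gate, rewind bitwise to the accepted
#' crossing frame, ramp the artificial disulfide restraints to full
#' strength, and install the permanent bond.  Only one disulfide forms per
#' segment; the loop restarts after each bond and runs until no reactive
#' pairs remain or the folding-time budget is exhausted.  Stage 3
#' (extension) is a conventional run of the fully bonded species.
#'
#' @param system list with \code{topology} and \code{frame} (e.g. from
#'   \code{\link{random_chain}})
#' @param config a \code{\link{controller_config}}
#' @param reduction a \code{\link{reduction_config}}; when enabled, every
#'   segment boundary makes one reduction decision per existing disulfide
#' @param store_frames logical; keep all stored frames in the result (turn
#'   off to save memory in large ensembles)
#' @return an object of class \code{redox_run}: list with \code{events}
#'   (one row per bond/reduction event in time order), \code{topology}
#'   (final), \code{status} (\code{"completed"} or
#'   \code{"unbonded-remaining"}), \code{frames}, \code{stage_boundaries}
#'   (ps), \code{config}
#' @export
run_oxidative_folding <- function(system, config = controller_config(),
                                  reduction = reduction_config(),
                                  store_frames = TRUE) {
  top <- system$topology
  frame <- system$frame
  set.seed(config$seed)
  if (is.null(frame$rng_state)) frame$rng_state <- seed_rng(config$seed)
  events <- .empty_events()
  frames <- list()
  keep <- function(fs) if (store_frames) frames <<- c(frames, fs)
  seg_args <- function(top, frame, len, idx)
    run_segment(frame, top, length_ps = len,
                frame_interval = config$frame_interval, dt = config$dt,
                gamma = config$gamma, temperature = config$temperature,
                segment_index = idx)

  # --- stage 1: equilibration under the standard potential ----------------
  top <- set_lj_mask(top, FALSE)
  t0 <- frame$time
  if (config$stage_lengths[["equilibration"]] > 0) {
    seg <- seg_args(top, frame, config$stage_lengths[["equilibration"]], 0L)
    frame <- seg$frames[[length(seg$frames)]]
    keep(seg$frames)
  }
  stage1_end <- frame$time

  # --- stage 2: reactive folding ------------------------------------------
  top <- set_lj_mask(top, TRUE)
  fold_budget <- config$stage_lengths[["folding"]]
  draws <- 0L
  seg_idx <- 0L
  while (length(top$reactive_sites) >= 2 &&
         frame$time - stage1_end < fold_budget - 1e-9) {
    seg_idx <- seg_idx + 1L
    len <- min(config$segment_length,
               fold_budget - (frame$time - stage1_end))
    len <- max(config$frame_interval,
               round(len / config$frame_interval) * config$frame_interval)
    seg <- seg_args(top, frame, len, seg_idx)
    scan <- .scan_segment(seg, top, config, draws)
    draws <- scan$draws
    if (is.null(scan$accepted)) {
      frame <- seg$frames[[length(seg$frames)]]
      keep(seg$frames)
    } else {
      acc <- scan$accepted
      keep(seg$frames[seq_len(acc$frame_index)])
      state <- rewind_to_crossing(seg, acc$frame_index, top)
      ramp <- run_ramp(state, top, acc$pair, schedule = config$ramp,
                       config = config)
      keep(ramp$frames)
      events <- rbind(events, .event_row(state, acc$pair, top, acc$distance,
                                         acc$gate_draws, "formed",
                                         acc$frame_index))
      top <- form_disulfide(top, acc$pair, ramp$terms)
      frame <- ramp$frame
      draws <- 0L
    }
    if (reduction$enabled) {
      red <- maybe_reduce(top, frame, reduction)
      top <- red$topology
      if (nrow(red$events)) events <- rbind(events, red$events)
    }
  }
  stage2_end <- frame$time
  status <- if (length(top$reactive_sites) >= 2) "unbonded-remaining"
            else "completed"

  # --- stage 3: conventional extension of the fully bonded species --------
  top <- set_lj_mask(top, FALSE)
  if (status == "completed" && config$stage_lengths[["extension"]] > 0) {
    seg <- seg_args(top, frame, config$stage_lengths[["extension"]], -1L)
    frame <- seg$frames[[length(seg$frames)]]
    keep(seg$frames)
  }

  structure(list(events = events, topology = top, status = status,
                 frames = frames, final_frame = frame,
                 stage_boundaries = c(start = t0, folding = stage1_end,
                                      extension = stage2_end,
                                      end = frame$time),
                 config = config), class = "redox_run")
}

#' @export
print.redox_run <- function(x, ...) {
  cat("Oxidative-folding run:", x$status, "\n")
  cat(sprintf("  stages (ps): equilibration %g..%g, folding ..%g, end %g\n",
              x$stage_boundaries["start"], x$stage_boundaries["folding"],
              x$stage_boundaries["extension"], x$stage_boundaries["end"]))
  formed <- x$events[x$events$kind == "formed", , drop = FALSE]
  if (nrow(formed)) {
    for (t in seq_len(nrow(formed)))
      cat(sprintf("  bond C%d-C%d at %.1f ps (r = %.3f A, %d rejected draws)\n",
                  formed$res_i[t], formed$res_j[t], formed$time[t],
                  formed$distance[t], formed$gate_draws[t]))
  } else cat("  no disulfides formed\n")
  if (any(x$events$kind == "reduced"))
    cat(" ", sum(x$events$kind == "reduced"), "reduction events\n")
  invisible(x)
}

#' @export
summary.redox_run <- function(object, ...) {
  formed <- object$events[object$events$kind == "formed", , drop = FALSE]
  top <- object$topology
  ss_res <- lapply(seq_len(nrow(top$disulfides)), function(t)
    top$particles$resid[top$disulfides[t, ]])
  res <- list(status = object$status, n_formed = nrow(formed),
              n_reduced = sum(object$events$kind == "reduced"),
              t_first = if (nrow(formed) >= 1)
                formed$time[1] - object$stage_boundaries[["folding"]]
              else NA_real_,
              t_second = if (nrow(formed) >= 2)
                formed$time[2] - object$stage_boundaries[["folding"]]
              else NA_real_,
              isomer = classify_isomer(
                ss_res,
                cys_positions = sort(top$particles$resid[
                  top$particles$name == "SG"])))
  class(res) <- "summary.redox_run"
  res
}

#' @export
print.summary.redox_run <- function(x, ...) {
  cat("status:", x$status, " bonds formed:", x$n_formed,
      " reduced:", x$n_reduced, "\n")
  cat(sprintf("first bond at %.1f ps, second at %.1f ps (folding clock)\n",
              x$t_first, x$t_second))
  cat("isomer:", x$isomer$label, "\n")
  invisible(x)
}

#' @export
plot.redox_run <- function(x, ...) {
  if (!length(x$frames))
    stop("run stored no frames (store_frames = FALSE)")
  top0 <- x$topology
  sg <- which(top0$particles$name == "SG")
  if (length(sg) < 2) stop("no sulfur pairs to plot")
  pairs <- t(combn(sg, 2))
  times <- vapply(x$frames, function(f) f$time, numeric(1))
  d <- t(vapply(x$frames, function(f)
    sqrt(rowSums((f$positions[pairs[, 1], , drop = FALSE] -
                    f$positions[pairs[, 2], , drop = FALSE])^2)),
    numeric(nrow(pairs))))
  lab <- paste0("C", top0$particles$resid[pairs[, 1]], "-C",
                top0$particles$resid[pairs[, 2]])
  matplot(times, d, type = "l", lty = 1, xlab = "time (ps)",
          ylab = "S-S distance (A)", ...)
  abline(h = 2.5, lty = 3)
  ev <- x$events[x$events$kind == "formed", , drop = FALSE]
  if (nrow(ev)) abline(v = ev$time, col = "red", lty = 2)
  legend("topright", legend = lab, col = seq_len(nrow(pairs)), lty = 1,
         cex = 0.7)
  invisible(x)
}
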