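# Independent oracles and small builders shared across tests.

# Quaternion (Horn) superposition RMSD: closed-form eigenvalue method,
# independent of the SVD-based implementation it cross-checks.
quat_rmsd <- function(P, Q) {
  P <- scale(P, scale = FALSE)
  Q <- scale(Q, scale = FALSE)
  S <- t(P) %*% Q
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max(0, (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# A topology of n free sulfur beads with the given reactive sites, for
# capture-detection tests on hand-built frames.
free_sulfur_topology <- function(n, reactive) {
  top <- cg_topology(
    particles = data.frame(name = rep("SG", n), resid = seq_len(n),
                           mass = rep(32.06, n)),
    bonds = NULL, residue_labels = ifelse(seq_len(n) %in% reactive,
                                          "CYR", "ALA"),
    reactive_sites = reactive)
  set_lj_mask(top, TRUE)
}

# Frames with all beads far apart (bead i at x = 40 i), then selected pairs
# moved to the requested distance in selected frames.
spread_frames <- function(top, n_frames, contacts = list()) {
  n <- top$n_particles
  base <- cbind(40 * seq_len(n), 0, 0)
  lapply(seq_len(n_frames), function(f) {
    x <- base
    for (ct in contacts) {
      if (ct$frame == f)
        x[ct$pair[2], ] <- x[ct$pair[1], ] + c(ct$distance, 0, 0)
    }
    new_frame(f, x)
  })
}

as_segment <- function(frames, start_frame = NULL) {
  structure(list(start_frame = start_frame, frames = frames,
                 segment_index = 1L, engine_args = NULL),
            class = "cg_segment")
}

angle_deg_of <- function(x, i, j, k) {
  u <- x[i, ] - x[j, ]; v <- x[k, ] - x[j, ]
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

pair_dist <- function(frame, pair) {
  sqrt(sum((frame$positions[pair[1], ] - frame$positions[pair[2], ])^2))
}

# Small controller config for fast mechanism tests.
quick_config <- function(seed = 1, ...) {
  controller_config(seed = seed,
                    stage_lengths = c(equilibration = 20, folding = 400,
                                      extension = 20),
                    segment_length = 100, ...)
}
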