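# Readers/writers: PDB subset, XYZ trajectories, YAML config, NOE tables,
# JSON-lines event logs, full-precision state files, run manifests.
# External residue numbering is 1-based (PDB convention); conversion to
# particle indices is confined to this layer.

#' Write a multi-model PDB subset
#'
#' Writes CA and SG beads as ATOM records, one MODEL per frame, with residue
#' names taken from the topology labels (CYR for reactive, CYX for bonded
#' cysteines).  Coordinates carry the standard 3 decimal places, so a
#' write/read round trip preserves them to 1e-3 A.
#'
#' @param frames a \code{cg_frame} or list of frames
#' @param top a \code{cg_topology}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_pdb <- function(frames, top, path) {
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  res3 <- substr(top$residue_labels, 1, 3)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1
  for (m in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    x <- frames[[m]]$positions
    for (i in seq_len(top$n_particles)) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, paste0(" ", top$particles$name[i]),
        res3[top$particles$resid[i]], top$particles$resid[i],
        x[i, 1], x[i, 2], x[i, 3],
        if (top$particles$name[i] == "SG") "S" else "C"), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Light validation pass so malformed ATOM records are reported with their
# line number before the file is handed to the parser.
.prescan_pdb <- function(path) {
  lines <- readLines(path)
  for (ln in seq_along(lines)) {
    l <- lines[ln]
    if (!startsWith(l, "ATOM") && !startsWith(l, "HETATM")) next
    if (nchar(l) < 54)
      stop("PDB parse error at line ", ln, ": record too short")
    coords <- suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                            substr(l, 39, 46),
                                            substr(l, 47, 54))))
    if (any(is.na(coords)))
      stop("PDB parse error at line ", ln, ": unreadable coordinates")
  }
  invisible(TRUE)
}

#' Read a PDB file as a coarse-grained system
#'
#' Imports CA and SG atoms only (all other atoms are ignored), preserving
#' the file's 1-based residue numbering.  Residues named CYR contribute
#' reactive sulfurs; CYX sulfurs are paired into disulfides by smallest S-S
#' distance.  Multi-model files become a conformer list suitable for
#' \code{\link{ensemble_rmsd}}.
#'
#' @param path PDB file
#' @return list with \code{topology}, \code{frame} (first model) and
#'   \code{conformers} (list of \code{cg_frame}, one per model)
#' @export
read_pdb_subset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  .prescan_pdb(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- which(pdb$atom$elety %in% c("CA", "SG"))
  if (!length(sel)) stop("no CA or SG atoms in ", path)
  atom <- pdb$atom[sel, ]
  ord <- order(match(atom$elety, c("CA", "SG")), atom$resno)
  atom <- atom[ord, ]
  resno <- sort(unique(atom$resno))
  resmap <- match(atom$resno, resno)
  labels <- rep("ALA", length(resno))
  for (r in seq_along(resno)) {
    nm <- atom$resid[resmap == r][1]
    labels[r] <- if (nm %in% c("CYR", "CYX")) nm else "ALA"
  }
  particles <- data.frame(name = atom$elety, resid = resmap,
                          mass = ifelse(atom$elety == "SG", .sg_mass,
                                        .bb_mass))
  # bonds: consecutive CA, plus each SG to its residue's CA
  ca <- which(particles$name == "CA")
  bonds <- NULL
  if (length(ca) >= 2)
    bonds <- data.frame(i = ca[-length(ca)], j = ca[-1], k = .bb_bond_k,
                        r0 = 3.8)
  for (sg in which(particles$name == "SG")) {
    host <- ca[particles$resid[ca] == particles$resid[sg]]
    if (length(host))
      bonds <- rbind(bonds, data.frame(i = host[1], j = sg, k = .sg_bond_k,
                                       r0 = .sg_bond_r0))
  }
  angles <- if (length(ca) >= 3)
    data.frame(i = ca[seq_len(length(ca) - 2)], j = ca[2:(length(ca) - 1)],
               k = ca[3:length(ca)], kf = .bb_angle_k,
               theta0 = .bb_angle_t0)
  else NULL
  reactive <- which(particles$name == "SG" &
                      labels[particles$resid] == "CYR")
  top <- cg_topology(particles = particles, bonds = bonds,
                     residue_labels = labels, angles = angles,
                     reactive_sites = reactive)
  # coordinates per model
  nm <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, 1)
  conformers <- lapply(seq_len(nm), function(m) {
    x <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)[sel, , drop = FALSE]
    new_frame(0, x[ord, , drop = FALSE])
  })
  # pair CYX sulfurs into disulfides by distance
  cyx_sg <- which(particles$name == "SG" & labels[particles$resid] == "CYX")
  while (length(cyx_sg) >= 2) {
    x <- conformers[[1]]$positions
    d <- as.matrix(dist(x[cyx_sg, , drop = FALSE]))
    diag(d) <- Inf
    hit <- which(d == min(d), arr.ind = TRUE)[1, ]
    pair <- sort(cyx_sg[hit])
    top$reactive_sites <- sort(union(top$reactive_sites, pair))
    top <- form_disulfide(top, pair)
    cyx_sg <- setdiff(cyx_sg, pair)
  }
  list(topology = top, frame = conformers[[1]], conformers = conformers)
}

#' Write / read an XYZ trajectory with a sidecar index
#'
#' Plain XYZ-per-frame format (element, x, y, z at full precision) with a
#' tab-separated sidecar index \code{<path>.idx} holding frame number,
#' time, restraint scale alpha and topology version, so a trajectory can be
#' re-read losslessly without the originating run object.
#'
#' @param frames list of \code{cg_frame}
#' @param top a \code{cg_topology}
#' @param path output file (index written to \code{paste0(path, ".idx")})
#' @param alpha optional numeric vector of restraint scales per frame
#' @param version optional integer vector of topology versions per frame
#' @return \code{path}, invisibly
#' @export
write_xyz <- function(frames, top, path, alpha = 0, version = 1L) {
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  alpha <- rep_len(alpha, length(frames))
  version <- rep_len(version, length(frames))
  el <- ifelse(top$particles$name == "SG", "S", "C")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    x <- frames[[f]]$positions
    writeLines(as.character(top$n_particles), con)
    writeLines(sprintf("frame %d t= %s ps", f,
                       format(frames[[f]]$time, digits = 17)), con)
    writeLines(sprintf("%-2s %s %s %s", el,
                       sprintf("%.17g", x[, 1]), sprintf("%.17g", x[, 2]),
                       sprintf("%.17g", x[, 3])), con)
  }
  idx <- data.frame(frame = seq_along(frames),
                    time = vapply(frames, function(f) f$time, numeric(1)),
                    alpha = alpha, version = version)
  write.table(idx, paste0(path, ".idx"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  idx <- read.delim(paste0(path, ".idx"))
  frames <- list()
  p <- 1
  while (p <= length(lines)) {
    n <- as.integer(lines[p])
    f <- length(frames) + 1L
    block <- lines[(p + 2):(p + 1 + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "[ ]+"))
    x <- matrix(as.numeric(parts[, 2:4]), ncol = 3)
    frames[[f]] <- new_frame(idx$time[f], x)
    p <- p + 2 + n
  }
  list(frames = frames, index = idx)
}

#' Serialize / restore a full simulation state
#'
#' JSON state file carrying the topology (including mutations: disulfides,
#' reactive registry, mask) and a frame at full floating-point precision
#' (17 significant digits, RNG state as hex), so that write followed by
#' read reproduces the objects bit-exactly and a run can be restarted from
#' the file.
#'
#' @param top a \code{cg_topology}
#' @param frame a \code{cg_frame}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_state <- function(top, frame, path) {
  ser <- list(
    topology = list(
      residue_labels = top$residue_labels,
      particles = top$particles,
      bonds = top$bonds, angles = top$angles, dihedrals = top$dihedrals,
      reactive_sites = top$reactive_sites,
      disulfides = as.integer(t(top$disulfides)),
      disulfide_terms = top$disulfide_terms,
      lj = unclass(top$lj), lj_mode = top$lj_mode,
      mask_active = top$mask_active,
      sphere_radius = top$sphere_radius, version = top$version),
    # frame numerics as %.17g strings: decimal JSON numbers do not
    # round-trip doubles bit-exactly, 17 significant digits do
    frame = list(time = sprintf("%.17g", frame$time),
                 positions = sprintf("%.17g", as.vector(frame$positions)),
                 velocities = sprintf("%.17g", as.vector(frame$velocities)),
                 rng_state = if (is.null(frame$rng_state)) NULL
                             else paste(format(frame$rng_state),
                                        collapse = "")))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_state
#' @return for \code{read_state}: list with \code{topology} and
#'   \code{frame}
#' @export
read_state <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- ser$topology
  fix_df <- function(df) {
    if (is.null(df) || length(df) == 0 || NROW(df) == 0) return(NULL)
    as.data.frame(df)
  }
  top <- cg_topology(particles = as.data.frame(st$particles),
                     bonds = fix_df(st$bonds),
                     residue_labels = st$residue_labels,
                     angles = fix_df(st$angles),
                     dihedrals = fix_df(st$dihedrals),
                     reactive_sites = st$reactive_sites,
                     lj = do.call(lj_params, as.list(st$lj)),
                     lj_mode = st$lj_mode,
                     sphere_radius = st$sphere_radius)
  if (length(st$disulfides))
    top$disulfides <- matrix(as.integer(st$disulfides), ncol = 2,
                             byrow = TRUE)
  if (length(st$disulfide_terms))
    top$disulfide_terms <- lapply(st$disulfide_terms, function(tm)
      lapply(tm, as.data.frame))
  top$version <- st$version
  top <- set_lj_mask(top, isTRUE(st$mask_active))
  n <- top$n_particles
  fr <- ser$frame
  rng <- NULL
  if (!is.null(fr$rng_state) && !is.na(fr$rng_state)) {
    hex <- fr$rng_state
    rng <- as.raw(strtoi(substring(hex, seq(1, nchar(hex), 2),
                                   seq(2, nchar(hex), 2)), 16L))
  }
  frame <- new_frame(as.numeric(fr$time),
                     matrix(as.numeric(fr$positions), n, 3),
                     matrix(as.numeric(fr$velocities), n, 3), rng)
  list(topology = top, frame = frame)
}

#' Write / read a bond-event log
#'
#' Line-delimited JSON, one record per bond or reduction event (time, frame
#' index, particle and residue pairs, trigger distance, rejected gate
#' draws, kind).  Full floating-point precision, so the log round-trips
#' losslessly.
#'
#' @param events event data frame (see \code{\link{run_oxidative_folding}})
#' @param path output file
#' @return \code{path} (write) / the event data frame (read)
#' @export
write_event_log <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(nrow(events))) {
    rec <- as.list(events[t, ])
    # doubles as %.17g strings so the log round-trips bit-exactly
    for (k in names(rec))
      if (is.double(rec[[k]])) rec[[k]] <- sprintf("%.17g", rec[[k]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(.empty_events())
  rows <- lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l)
    r[vapply(r, is.null, TRUE)] <- NA
    for (k in c("time", "distance"))
      if (!is.null(r[[k]])) r[[k]] <- as.numeric(r[[k]])
    as.data.frame(r)
  })
  out <- do.call(rbind, rows)
  out$frame <- as.integer(out$frame)
  for (k in c("particle_i", "particle_j", "res_i", "res_j", "gate_draws"))
    out[[k]] <- as.integer(out[[k]])
  out
}

#' Read an NOE restraint table
#'
#' Tab-separated columns \code{group_a}, \code{group_b}, \code{r_low},
#' \code{r_high}.  Selectors use \code{residue:atom} syntax with 1-based
#' residue numbers; a \code{*} wildcard in the atom part or a
#' comma-separated selector list encodes ambiguous/equivalent protons.
#'
#' @param path TSV file (header optional if columns are in the above order)
#' @return list of \code{\link{noe_restraint}} objects
#' @export
read_noe_table <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("group_a", first)
  df <- read.delim(path, header = header,
                   col.names = c("group_a", "group_b", "r_low", "r_high"),
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(t)
    noe_restraint(strsplit(df$group_a[t], ",")[[1]],
                  strsplit(df$group_b[t], ",")[[1]],
                  df$r_low[t], df$r_high[t]))
}

#' Read a run configuration file
#'
#' YAML key-value schema; unknown keys are rejected with an error listing
#' them.  Top-level keys: \code{preset} (\code{"guanylin"}), \code{seed},
#' \code{temperature}, \code{gamma}, \code{dt}, \code{capture_radius},
#' \code{accept_prob}, \code{segment_length}, \code{frame_interval},
#' \code{lj_mode}, \code{stage_lengths} (mapping with
#' \code{equilibration}/\code{folding}/\code{extension}), \code{ramp}
#' (\code{n_steps}/\code{step_duration}), \code{chain}
#' (\code{n_residues}/\code{reactive_positions}/\code{bond_length}),
#' \code{reduction} (\code{enabled}/\code{base_prob}/\code{exposure_fn}).
#' All omitted keys take the documented defaults.
#'
#' @param path YAML file
#' @return list with \code{config} (\code{\link{controller_config}}),
#'   \code{chain} (\code{\link{chain_spec}}), \code{reduction}
#'   (\code{\link{reduction_config}})
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("preset", "seed", "temperature", "gamma", "dt",
             "capture_radius", "accept_prob", "segment_length",
             "frame_interval", "lj_mode", "stage_lengths", "ramp", "chain",
             "reduction")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("config error: unknown keys: ", paste(bad, collapse = ", "))
  check_sub <- function(x, known, where) {
    bad <- setdiff(names(x), known)
    if (length(bad))
      stop("config error: unknown keys in ", where, ": ",
           paste(bad, collapse = ", "))
  }
  seed <- raw$seed %||% 1
  chain_args <- list(n_residues = 15,
                     reactive_positions = c(4, 7, 12, 15),
                     bond_length = 3.8)
  if (!is.null(raw$preset)) {
    if (!identical(raw$preset, "guanylin"))
      stop("config error: unknown preset '", raw$preset, "'")
  }
  if (!is.null(raw$chain)) {
    check_sub(raw$chain, c("n_residues", "reactive_positions",
                           "bond_length"), "chain")
    chain_args[names(raw$chain)] <- raw$chain
  }
  chain <- do.call(chain_spec, c(chain_args, list(seed = seed)))
  ramp_args <- list()
  if (!is.null(raw$ramp)) {
    check_sub(raw$ramp, c("n_steps", "step_duration"), "ramp")
    ramp_args <- raw$ramp
  }
  stage <- stage_preset("desk")
  if (!is.null(raw$stage_lengths)) {
    check_sub(raw$stage_lengths, c("equilibration", "folding", "extension"),
              "stage_lengths")
    stage[names(raw$stage_lengths)] <- unlist(raw$stage_lengths)
  }
  cfg_args <- raw[intersect(names(raw),
                            c("capture_radius", "accept_prob",
                              "segment_length", "frame_interval", "lj_mode",
                              "temperature", "gamma", "dt"))]
  config <- do.call(controller_config,
                    c(cfg_args, list(stage_lengths = stage, seed = seed,
                                     ramp = do.call(ramp_schedule,
                                                    ramp_args))))
  red_args <- list()
  if (!is.null(raw$reduction)) {
    check_sub(raw$reduction, c("enabled", "base_prob", "exposure_fn"),
              "reduction")
    red_args <- raw$reduction
  }
  list(config = config, chain = chain,
       reduction = do.call(reduction_config, red_args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / verify a run manifest
#'
#' JSON manifest with the configuration snapshot, seed, package version,
#' stage boundaries and the MD5 checksum of every output file, so a run
#' directory can be validated on re-read.
#'
#' @param dir run output directory
#' @param config a \code{\link{controller_config}}
#' @param files character vector of file paths to checksum
#' @param stage_boundaries named numeric vector, ps
#' @return the manifest path, invisibly
#' @export
write_manifest <- function(dir, config, files,
                           stage_boundaries = NULL) {
  man <- list(package = "redoxfold",
              version = as.character(packageVersion("redoxfold")),
              seed = config$seed,
              config = unclass(config)[setdiff(names(unclass(config)),
                                               "ramp")],
              ramp = unclass(config$ramp),
              stage_boundaries = stage_boundaries,
              files = lapply(files, function(f)
                list(name = basename(f),
                     md5 = unname(tools::md5sum(f)))))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @param path manifest path
#' @param verify check file checksums against the directory contents
#' @return for \code{read_manifest}: the manifest list
#' @export
read_manifest <- function(path, verify = TRUE) {
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (verify) {
    for (f in man$files) {
      fp <- file.path(dirname(path), f$name)
      if (!file.exists(fp)) stop("manifest error: missing file ", f$name)
      if (!identical(unname(tools::md5sum(fp)), f$md5))
        stop("manifest error: checksum mismatch for ", f$name)
    }
  }
  man
}
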