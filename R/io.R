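# File formats and the build -> analyze -> report pipeline.
#
# GRO (fixed width, nm) is the canonical interchange format; PDB (Angstrom,
# via bio3d) is offered for visualisation; DCD trajectories are read through
# bio3d against a GRO/PDB topology frame. Multi-frame trajectories can also
# travel as concatenated GRO frames with "t= <ps>" in the title line.

.SPECIES_FROM_RESNAME <- c(POPC = "POPC", CHOL = "CHOL", OX1 = "OX1",
                           OX2 = "OX2", OX3A = "OX3a", OX3B = "OX3b",
                           SOL = "SOL")

# name -> (element, mass) lookup across all templates + water sites
.particle_lookup <- function() {
  tpl <- default_templates()
  df <- do.call(rbind, lapply(tpl, function(t) t$particles[c("name", "element", "mass")]))
  df <- rbind(df, data.frame(name = c("OW", "HW1", "HW2"),
                             element = c("O", "H", "H"),
                             mass = c(15.999, 1.008, 1.008)))
  df[!duplicated(df$name), ]
}

#' Write a frame or trajectory as GRO
#'
#' Fixed-width GROMACS GRO records, coordinates in nm to three decimals.
#' A trajectory is written as concatenated frames with the time in each
#' title line (`t= <ps>`).
#'
#' @param x A `bilayer_frame` or `bilayer_trajectory`.
#' @param path Output path.
#' @export
write_gro <- function(x, path) {
  if (inherits(x, "bilayer_frame")) x <- as_trajectory(x)
  stopifnot(inherits(x, "bilayer_trajectory"))
  p <- x$particles
  con <- file(path, "w")
  on.exit(close(con))
  for (f in x$frames) {
    writeLines(sprintf("oxbilayer frame t= %.3f ps", f$time), con)
    writeLines(sprintf("%5d", nrow(p)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       p$resid %% 100000L, toupper(p$resname),
                       substr(p$name, 1, 5), seq_len(nrow(p)) %% 100000L,
                       f$xyz[, 1], f$xyz[, 2], f$xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", f$box[1], f$box[2], f$box[3]), con)
  }
  invisible(path)
}

.parse_gro_frames <- function(lines, path) {
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    title <- lines[i]
    n <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(n) || n < 1) {
      stop("malformed GRO atom count at line ", i + 1, " of ", path)
    }
    if (i + 1 + n + 1 > length(lines)) {
      stop("truncated GRO frame starting at line ", i, " of ", path)
    }
    rec <- lines[(i + 2):(i + 1 + n)]
    resid <- suppressWarnings(as.integer(substr(rec, 1, 5)))
    resname <- trimws(substr(rec, 6, 10))
    name <- trimws(substr(rec, 11, 15))
    xyz <- suppressWarnings(cbind(as.numeric(substr(rec, 21, 28)),
                                  as.numeric(substr(rec, 29, 36)),
                                  as.numeric(substr(rec, 37, 44))))
    if (anyNA(resid) || anyNA(xyz)) {
      bad <- i + 1 + which(is.na(resid) | rowSums(is.na(xyz)) > 0)[1]
      stop("malformed fixed-width GRO record at line ", bad, " of ", path)
    }
    box <- as.numeric(strsplit(trimws(lines[i + 2 + n]), "\\s+")[[1]])[1:3]
    if (anyNA(box)) stop("malformed GRO box line at line ", i + 2 + n, " of ", path)
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_
    frames[[length(frames) + 1]] <- list(time = time, box = box, xyz = xyz,
                                         resid = resid, resname = resname,
                                         name = name)
    i <- i + 2 + n + 1
  }
  if (!length(frames)) stop("no frames found in ", path, " (empty file?)")
  frames
}

.particles_from_records <- function(resid, resname, name) {
  lookup <- .particle_lookup()
  li <- match(name, lookup$name)
  if (anyNA(li)) {
    stop("unknown particle name(s): ",
         paste(utils::head(unique(name[is.na(li)]), 5), collapse = ", "))
  }
  species <- .SPECIES_FROM_RESNAME[toupper(resname)]
  if (anyNA(species)) {
    stop("unknown residue name(s): ",
         paste(utils::head(unique(resname[is.na(species)]), 5), collapse = ", "))
  }
  is_lipid <- species != "SOL"
  data.frame(name = name, element = lookup$element[li], mass = lookup$mass[li],
             resname = toupper(resname), resid = resid,
             lipid_id = ifelse(is_lipid, resid, NA_integer_),
             species = unname(species), stringsAsFactors = FALSE)
}

#' Read a GRO file
#'
#' @param path GRO file (one or more concatenated frames).
#' @return A `bilayer_frame` for a single-frame file, otherwise a
#'   `bilayer_trajectory` (frame times from the `t=` title tag, or the frame
#'   index if absent).
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  frames <- .parse_gro_frames(lines, path)
  p <- .particles_from_records(frames[[1]]$resid, frames[[1]]$resname,
                               frames[[1]]$name)
  if (length(frames) == 1) {
    return(bilayer_frame(p, frames[[1]]$xyz, frames[[1]]$box))
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (anyNA(times)) times <- seq_along(frames)
  bilayer_trajectory(p, lapply(seq_along(frames), function(i) {
    list(time = times[i], box = frames[[i]]$box, xyz = frames[[i]]$xyz)
  }))
}

#' Write a frame as PDB (Angstrom)
#'
#' Standard fixed-column ATOM records (four-character lipid residue names in
#' columns 18-21) with a CRYST1 box record; readable by [read_pdb_frame()]
#' and by bio3d.
#'
#' @param frame A `bilayer_frame`.
#' @param path Output path.
#' @export
write_pdb_frame <- function(frame, path) {
  stopifnot(inherits(frame, "bilayer_frame"))
  p <- frame$particles
  xyz <- frame$xyz * 10
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     frame$box[1] * 10, frame$box[2] * 10, frame$box[3] * 10), con)
  writeLines(sprintf("ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
                     seq_len(nrow(p)) %% 100000L, substr(p$name, 1, 4),
                     toupper(p$resname), p$resid %% 10000L,
                     xyz[, 1], xyz[, 2], xyz[, 3]), con)
  writeLines("END", con)
  invisible(path)
}

#' Read a PDB file as a frame (coordinates converted to nm)
#' @param path PDB file.
#' @param box Box edges in nm (PDB CRYST1 is not relied upon; supply the box
#'   or accept a bounding-box estimate).
#' @export
read_pdb_frame <- function(path, box = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  xyz <- cbind(a$x, a$y, a$z) / 10
  if (is.null(box)) box <- apply(xyz, 2, max) + 0.1
  p <- .particles_from_records(a$resno, a$resid, a$elety)
  bilayer_frame(p, xyz, box)
}

#' Read a DCD trajectory against a topology frame
#'
#' @param path DCD file.
#' @param topology A `bilayer_frame` (e.g. from [read_gro()]) supplying the
#'   particle table and box.
#' @param dt Frame spacing in ps (default 100, the usual recording cadence).
#' @export
read_dcd_trajectory <- function(path, topology, dt = 100) {
  stopifnot(inherits(topology, "bilayer_frame"))
  if (!file.exists(path)) stop("no such file: ", path)
  m <- bio3d::read.dcd(path, verbose = FALSE)
  n <- nrow(topology$particles)
  if (ncol(m) != 3 * n) {
    stop("DCD has ", ncol(m) / 3, " atoms; topology has ", n)
  }
  bilayer_trajectory(topology$particles, lapply(seq_len(nrow(m)), function(i) {
    list(time = i * dt, box = topology$box,
         xyz = matrix(m[i, ], ncol = 3, byrow = TRUE) / 10)
  }))
}

# ---- pipeline ---------------------------------------------------------------

.require_keys <- function(config, keys) {
  miss <- setdiff(keys, names(config))
  if (length(miss)) {
    stop("config is missing required key(s): ", paste(miss, collapse = ", "))
  }
}

#' Run the full analysis pipeline from a configuration
#'
#' Either generates a synthetic trajectory (`mode: synthetic`, parameters
#' under `synthetic:` passed to [synthetic_spec()]) or reads one
#' (`mode: analyze`, `input:` with `trajectory` and optionally `topology`),
#' then runs the analysis battery -- area per lipid, phosphate density
#' profile and thickness, sn-1 order parameters, core water density, pore
#' detection -- and writes TSV profiles, a key-value report, a plain-text
#' report and a log echoing the configuration, all under `outdir`.
#'
#' @param config A named list or the path to a YAML file. Required keys:
#'   `mode`, `outdir`, `seed`. Optional `analysis:` keys: `n_bins`,
#'   `equil_time`, `half_width`, `link_cutoff`, `include_c2`,
#'   `n_per_leaflet`.
#' @return A `bilayer_report` (invisibly also written to `outdir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  .require_keys(config, c("mode", "outdir", "seed"))
  an <- config$analysis
  if (is.null(an)) an <- list()
  n_bins <- an$n_bins %||% 100
  equil_time <- an$equil_time
  half_width <- an$half_width %||% 0.5
  link_cutoff <- an$link_cutoff %||% 0.35
  include_c2 <- an$include_c2 %||% TRUE

  if (config$mode == "synthetic") {
    sargs <- config$synthetic
    if (is.null(sargs)) sargs <- list()
    sargs$seed <- config$seed
    spec <- do.call(synthetic_spec, sargs)
    traj <- gen_bilayer_trajectory(spec)$trajectory
  } else if (config$mode == "analyze") {
    .require_keys(config, "input")
    inp <- config$input
    .require_keys(inp, "trajectory")
    traj <- if (grepl("\\.dcd$", inp$trajectory, ignore.case = TRUE)) {
      .require_keys(inp, "topology")
      read_dcd_trajectory(inp$trajectory, read_gro(inp$topology),
                          dt = inp$dt %||% 100)
    } else {
      x <- read_gro(inp$trajectory)
      if (inherits(x, "bilayer_frame")) as_trajectory(x) else x
    }
  } else {
    stop("mode must be 'synthetic' or 'analyze', got '", config$mode, "'")
  }

  p <- traj$particles
  n_lipids <- length(unique(stats::na.omit(p$lipid_id)))
  n_per_leaflet <- an$n_per_leaflet %||% (n_lipids / 2)

  apl <- tryCatch(area_per_lipid(traj, n_per_leaflet, equil_time),
                  error = function(e) stop("stage area_per_lipid: ",
                                           conditionMessage(e), call. = FALSE))
  p_prof <- tryCatch(density_profile(traj, phosphate_selection, n_bins, equil_time),
                     error = function(e) stop("stage density_profile(P): ",
                                              conditionMessage(e), call. = FALSE))
  thick <- tryCatch(bilayer_thickness(p_prof), error = function(e) NULL)
  ord <- tryCatch(order_parameter(traj, equil_time = equil_time,
                                  include_c2 = include_c2),
                  error = function(e) NULL)
  w_prof <- density_profile(traj, water_selection, n_bins, equil_time)
  w_core <- tryCatch(water_density_center(traj, equil_time, half_width),
                     error = function(e) NA_real_)
  pore <- detect_pore(traj, equil_time, link_cutoff)
  has_markers <- any(marker_selection(p))
  m_prof <- if (has_markers) {
    density_profile(traj, marker_selection, n_bins, equil_time)
  } else NULL

  report <- structure(list(
    n_lipids = n_lipids, n_per_leaflet = n_per_leaflet,
    n_frames = length(traj$frames),
    apl = apl, thickness = thick, order = ord,
    water_core = w_core, pore = pore,
    p_profile = p_prof, water_profile = w_prof, marker_profile = m_prof
  ), class = "bilayer_report")

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  .write_report_files(report, config)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_profile_tsv <- function(prof, path, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# %s density profile", what),
               "# bin_center: nm relative to the bilayer midplane",
               "# density: kg m^-3"), con)
  utils::write.table(prof, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_report_files <- function(report, config) {
  out <- config$outdir
  .write_profile_tsv(report$p_profile, file.path(out, "p_density.tsv"), "phosphate")
  .write_profile_tsv(report$water_profile, file.path(out, "water_density.tsv"), "water")
  if (!is.null(report$marker_profile)) {
    .write_profile_tsv(report$marker_profile, file.path(out, "marker_density.tsv"),
                       "oxidation marker")
  }
  if (!is.null(report$order)) {
    con <- file(file.path(out, "scd_per_carbon.tsv"), "w")
    writeLines(c("# sn-1 deuterium order parameter per chain carbon",
                 "# carbon: chain position; scd: dimensionless",
                 "carbon\tscd"), con)
    writeLines(sprintf("%s\t%.6f", names(report$order$per_carbon),
                       report$order$per_carbon), con)
    close(con)
  }
  kv <- c(
    sprintf("n_lipids\t%d\tcount", report$n_lipids),
    sprintf("n_per_leaflet\t%g\tcount", report$n_per_leaflet),
    sprintf("n_frames\t%d\tcount", report$n_frames),
    sprintf("area_per_lipid\t%.6f\tnm^2", report$apl$value),
    sprintf("area_per_lipid_error\t%.6f\tnm^2", report$apl$error),
    if (!is.null(report$thickness)) {
      c(sprintf("thickness\t%.6f\tnm", report$thickness$value),
        sprintf("thickness_error\t%.6f\tnm", report$thickness$error))
    } else "thickness\tNA\tnm",
    if (!is.null(report$order)) {
      sprintf("mean_scd\t%.6f\tdimensionless", report$order$mean_scd)
    },
    sprintf("core_water_density\t%.6f\tkg m^-3", report$water_core),
    sprintf("pore_spanning\t%s\tboolean", report$pore$spanning),
    if (isTRUE(report$pore$spanning)) {
      c(sprintf("pore_diameter_max\t%.3f\tAngstrom", report$pore$diameter_max),
        sprintf("pore_diameter_min\t%.3f\tAngstrom", report$pore$diameter_min),
        sprintf("pore_onset\t%g\tps", report$pore$frame_of_onset))
    }
  )
  writeLines(unlist(kv), file.path(out, "report.tsv"))
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out, "report.txt"))
  cfg <- utils::capture.output(utils::str(config, give.attr = FALSE))
  writeLines(c("# run configuration (seed included; sufficient to reproduce)", cfg),
             file.path(out, "log.txt"))
}

#' @export
print.bilayer_report <- function(x, ...) {
  cat("Bilayer analysis report\n")
  cat(sprintf("  lipids: %d (%g per leaflet), frames: %d\n",
              x$n_lipids, x$n_per_leaflet, x$n_frames))
  cat(sprintf("  area per lipid: %.4f +/- %.4f nm^2 [%s]\n",
              x$apl$value, x$apl$error, x$apl$method))
  if (!is.null(x$thickness)) {
    cat(sprintf("  thickness: %.3f +/- %.3f nm [P-peak distance]\n",
                x$thickness$value, x$thickness$error))
  } else {
    cat("  thickness: leaflet peaks unresolved\n")
  }
  if (!is.null(x$order)) {
    cat(sprintf("  mean sn-1 S_CD: %.4f (%d carbons)\n",
                x$order$mean_scd, length(x$order$per_carbon)))
  }
  cat(sprintf("  core water density: %.3f kg m^-3\n", x$water_core))
  if (isTRUE(x$pore$spanning)) {
    cat(sprintf("  pore: spanning, diameter %.1f-%.1f A (onset t = %g ps)\n",
                x$pore$diameter_min, x$pore$diameter_max, x$pore$frame_of_onset))
  } else if (identical(x$pore$spanning, FALSE)) {
    cat("  pore: none\n")
  } else {
    cat("  pore: membrane span unresolvable\n")
  }
  invisible(x)
}
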