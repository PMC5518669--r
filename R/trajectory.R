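# Containers: a single bilayer frame (packed configuration) and a trajectory
# (ordered frames sharing one particle table). Coordinates in nm, times in ps,
# box as a 3-vector of orthorhombic edge lengths in nm; z is the membrane
# normal by convention.

#' Construct a bilayer frame
#'
#' @param particles Data frame with one row per particle: `name`, `element`,
#'   `mass` (amu), `resname`, `resid` (file residue number), `lipid_id`
#'   (integer; shared by the OX3a/OX3b fragments of one oxidised lipid; NA for
#'   water), `species`.
#' @param xyz n x 3 coordinate matrix, nm.
#' @param box Length-3 numeric, box edges in nm.
#' @param leaflet Optional named vector (`"upper"`/`"lower"`) keyed by lipid id.
#' @export
bilayer_frame <- function(particles, xyz, box, leaflet = NULL) {
  stopifnot(is.data.frame(particles), is.matrix(xyz),
            nrow(particles) == nrow(xyz), ncol(xyz) == 3,
            length(box) == 3, all(box > 0))
  structure(list(particles = particles, xyz = xyz, box = as.numeric(box),
                 leaflet = leaflet),
            class = "bilayer_frame")
}

#' Construct a trajectory
#'
#' @param particles Shared particle table (see [bilayer_frame()]).
#' @param frames List of `list(time = ps, box = nm 3-vector, xyz = n x 3 nm)`.
#' @export
bilayer_trajectory <- function(particles, frames) {
  stopifnot(is.data.frame(particles), length(frames) >= 1)
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  n <- nrow(particles)
  ok <- vapply(frames, function(f) {
    is.matrix(f$xyz) && nrow(f$xyz) == n && ncol(f$xyz) == 3 &&
      length(f$box) == 3 && all(f$box > 0)
  }, logical(1))
  if (!all(ok)) stop("every frame needs an n x 3 xyz matrix and a 3-vector box")
  structure(list(particles = particles, frames = frames),
            class = "bilayer_trajectory")
}

#' Promote a frame to a one-frame trajectory
#' @param frame A `bilayer_frame`.
#' @param time Timestamp in ps.
#' @export
as_trajectory <- function(frame, time = 0) {
  bilayer_trajectory(frame$particles,
                     list(list(time = time, box = frame$box, xyz = frame$xyz)))
}

#' @export
print.bilayer_frame <- function(x, ...) {
  cat(sprintf("<bilayer_frame: %d particles, box %.2f x %.2f x %.2f nm>\n",
              nrow(x$particles), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' @export
print.bilayer_trajectory <- function(x, ...) {
  t0 <- x$frames[[1]]$time
  t1 <- x$frames[[length(x$frames)]]$time
  cat(sprintf("<bilayer_trajectory: %d particles, %d frames, t = %g..%g ps>\n",
              nrow(x$particles), length(x$frames), t0, t1))
  invisible(x)
}

#' Frame times of a trajectory (ps)
#' @param traj A `bilayer_trajectory`.
#' @export
frame_times <- function(traj) vapply(traj$frames, function(f) f$time, numeric(1))

# Frames strictly after the equilibration time.
.post_equil_frames <- function(traj, equil_time) {
  keep <- frame_times(traj) > equil_time
  if (!any(keep)) {
    stop("no frames after equilibration time ", equil_time, " ps")
  }
  traj$frames[keep]
}

# Periodic minimum-image displacement along one axis.
.pbc_wrap <- function(d, L) d - L * round(d / L)

# Logical selector for particles; `selection` may be a character vector of
# species/resnames, or a predicate function on the particle table.
.select_particles <- function(particles, selection) {
  if (is.function(selection)) {
    sel <- selection(particles)
    stopifnot(is.logical(sel), length(sel) == nrow(particles))
    sel
  } else if (is.character(selection)) {
    particles$species %in% selection | particles$resname %in% selection |
      particles$name %in% selection
  } else {
    stop("selection must be a character vector or a predicate function")
  }
}

#' Selector for phosphate (P) particles
#' @param particles Particle table of a frame/trajectory.
#' @export
phosphate_selection <- function(particles) particles$name == "P"

#' Selector for the polar oxidation-marker atoms (peroxide/aldehyde oxygens)
#' @param particles Particle table of a frame/trajectory.
#' @export
marker_selection <- function(particles) {
  particles$name %in% c("OA", "OB", "OA9", "OA1")
}

#' Selector for water particles
#' @param particles Particle table of a frame/trajectory.
#' @export
water_selection <- function(particles) particles$resname == "SOL"
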