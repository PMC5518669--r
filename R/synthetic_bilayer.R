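# Synthetic bilayer trajectories with exact ground truth for every analysis
# observable. The generator emulates the statistical structure the analysis
# assumes -- leaflet phosphate planes, tilted rigid all-trans sn-1 chains,
# NPT-like AR(1) box-area fluctuations, outer bulk-packed water slabs, bent
# versus linear oxidised-tail marker depths, and optional transmembrane water
# pores -- not the physics that produces it.

.BULK_WATER_KG_M3 <- .BULK_WATER_NM3 * 18.0150 * .AMU_NM3_TO_KG_M3

#' Specification of a synthetic bilayer trajectory
#'
#' Defaults correspond to the study conditions of the reference systems:
#' 72 lipids, 4000 waters, phosphate-plane separation 3.8 nm, area per lipid
#' 0.65 nm^2, frames every 100 ps.
#'
#' @param n_lipids Even total lipid count (default 72).
#' @param chol_fraction,ox_fraction,ox_species Composition as in
#'   [make_composition()].
#' @param n_water Water molecules in the outer slabs (default scales the
#'   reference 4000-per-72-lipids ratio).
#' @param leaflet_separation Distance between the two phosphate planes, nm
#'   (ground truth for the thickness; default 3.8).
#' @param tilt Fixed sn-1 chain tilt from the membrane normal, degrees
#'   (ground truth for S_CD via the rotational closed form; default 0).
#' @param tilt_sigma If non-NULL, per-lipid tilts are drawn as
#'   |N(0, tilt_sigma)| degrees instead of the fixed `tilt`.
#' @param apl_truth Area per lipid, nm^2; sets the mean lateral box area
#'   (default 0.65).
#' @param area_sigma Stationary SD of the AR(1) box-area series, nm^2.
#' @param area_phi AR(1) coefficient of the box-area series, in `[0, 1)`.
#' @param pore_radius Optional pore radius in Angstrom; a bulk-packed water
#'   cylinder of this radius spans the core.
#' @param polar_bend For oxidised species: TRUE places the polar markers near
#'   the phosphate planes (bent tails), FALSE at the bilayer midplane
#'   (linear tails, the post-oxidation starting state).
#' @param n_frames,frame_dt Number of frames and spacing in ps (defaults 20
#'   and 100).
#' @param box_z Box height, nm (default 11).
#' @param p_jitter SD of the phosphate z jitter about its plane, nm.
#' @param seed Integer seed; output is bit-identical for a fixed spec + seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_lipids = 72, chol_fraction = 0, ox_fraction = 0,
                           ox_species = "none", n_water = NULL,
                           leaflet_separation = 3.8, tilt = 0,
                           tilt_sigma = NULL, apl_truth = 0.65,
                           area_sigma = 0.25, area_phi = 0.8,
                           pore_radius = NULL, polar_bend = FALSE,
                           n_frames = 20, frame_dt = 100, box_z = 11,
                           p_jitter = 0.02, seed = 1) {
  stopifnot(n_lipids >= 2, n_lipids %% 2 == 0, leaflet_separation > 0,
            apl_truth > 0, area_sigma >= 0, n_frames >= 1, frame_dt > 0,
            box_z > leaflet_separation + 1, p_jitter >= 0)
  if (area_phi < 0 || area_phi >= 1) stop("area_phi must be in [0, 1)")
  if (is.null(n_water)) n_water <- round(n_lipids * 4000 / 72)
  a0 <- apl_truth * n_lipids / 2
  if (!is.null(pore_radius)) {
    if (pore_radius <= 0) stop("pore_radius must be positive")
    if (2 * pore_radius / 10 >= sqrt(a0)) {
      stop("pore (diameter ", 2 * pore_radius,
           " A) is wider than the lateral box")
    }
  }
  comp <- make_composition(n_lipids, chol_fraction, ox_fraction, ox_species,
                           n_water = n_water,
                           box = c(sqrt(a0), sqrt(a0), box_z))
  structure(list(
    composition = comp, leaflet_separation = leaflet_separation,
    tilt = tilt, tilt_sigma = tilt_sigma, apl_truth = apl_truth,
    area_sigma = area_sigma, area_phi = area_phi, pore_radius = pore_radius,
    polar_bend = polar_bend, n_frames = n_frames, frame_dt = frame_dt,
    box_z = box_z, p_jitter = p_jitter, seed = seed
  ), class = "synthetic_spec")
}

#' Stationary AR(1) series
#'
#' x_t = mean + phi (x_{t-1} - mean) + e_t with e_t ~ N(0, sigma^2 (1-phi^2)),
#' so `sigma` is the stationary standard deviation. The first value is drawn
#' from the stationary distribution. Deterministic per seed.
#'
#' @param n Length (>= 2 for a series; 1 is allowed for degenerate use).
#' @param mean Stationary mean.
#' @param sigma Stationary SD (>= 0).
#' @param phi AR(1) coefficient in `[0, 1)`.
#' @param seed Integer seed.
#' @export
gen_ar1_series <- function(n, mean = 0, sigma = 1, phi = 0, seed = 1) {
  stopifnot(n >= 1, sigma >= 0)
  if (phi < 0 || phi >= 1) stop("phi must be in [0, 1)")
  .with_seed(seed, {
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, sigma)
    if (n > 1) {
      e <- stats::rnorm(n - 1, 0, sigma * sqrt(1 - phi^2))
      for (t in 2:n) x[t] <- phi * x[t - 1] + e[t - 1]
    }
    x + mean
  })
}

#' Generate a synthetic bilayer trajectory with ground truth
#'
#' Phosphates sit on two jittered planes at +/- `leaflet_separation`/2 about
#' the box centre; sn-1 chains are rigid tetrahedral zig-zags tilted per spec
#' with a fresh uniform azimuth per lipid per frame; the lateral box area
#' follows the AR(1) law about `apl_truth` * n_per_leaflet; waters fill the
#' outer slabs at bulk packing; an optional bulk-packed water cylinder spans
#' the core. Lateral lipid positions are fixed in fractional coordinates, so
#' lipids do not overlap but also do not diffuse.
#'
#' @param spec A `synthetic_spec`.
#' @return List: `trajectory` (a `bilayer_trajectory`) and `truth` with
#'   `thickness` (nm), `apl` (nm^2), `apl_series` (per-frame nm^2),
#'   `mean_scd` (azimuth-averaged closed form -1/2 * P2(cos tilt), averaged
#'   over the realised per-lipid tilts), `core_water_density` (kg m^-3),
#'   `pore_diameter` (Angstrom or NULL), `marker_abs_z` (nm or NULL),
#'   `n_per_leaflet`.
#' @export
gen_bilayer_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, .gen_traj_impl(spec))
}

.gen_traj_impl <- function(spec) {
  comp <- spec$composition
  n_lip <- comp$n_lipids_total
  npl <- n_lip / 2
  z_mid <- spec$box_z / 2
  half_sep <- spec$leaflet_separation / 2
  templates <- default_templates()

  species <- c(rep("POPC", comp$n_popc), rep("CHOL", comp$n_chol),
               rep(comp$ox_species, comp$n_ox))
  species <- species[species != "none"]
  leaflet <- unlist(lapply(table(factor(species, unique(species))), function(k) {
    rep_len(c("upper", "lower"), k)
  }), use.names = FALSE)

  # fixed fractional lateral grid per leaflet (no overlap, no diffusion)
  frac_xy <- matrix(0, n_lip, 2)
  for (lf in c("upper", "lower")) {
    idx <- which(leaflet == lf)
    g <- ceiling(sqrt(length(idx)))
    gx <- ((seq_along(idx) - 1) %% g + 0.5) / g
    gy <- ((seq_along(idx) - 1) %/% g + 0.5) / g
    frac_xy[idx, ] <- cbind(gx, gy) +
      matrix(stats::runif(2 * length(idx), -0.1 / g, 0.1 / g), ncol = 2)
  }

  # per-lipid tilt (degrees); ground truth averages the rotational closed form
  has_sn1 <- vapply(species,
                    function(sp) sp %in% c("POPC", "OX1", "OX2", "OX3"),
                    logical(1))
  tilts <- if (is.null(spec$tilt_sigma)) {
    rep(spec$tilt, n_lip)
  } else {
    abs(stats::rnorm(n_lip, 0, spec$tilt_sigma))
  }
  p2 <- function(c) (3 * c^2 - 1) / 2
  mean_scd_truth <- if (any(has_sn1)) {
    mean(-0.5 * p2(cos(tilts[has_sn1] * pi / 180)))
  } else NA_real_

  # marker depth (leaflet-local z relative to the phosphate, negative = core)
  marker_z <- if (comp$ox_species == "none") NULL
              else if (spec$polar_bend) -0.12 else -half_sep

  a0 <- spec$apl_truth * npl
  areas <- gen_ar1_series(spec$n_frames, a0, spec$area_sigma, spec$area_phi,
                          seed = stats::runif(1, 1, 2^30))
  areas <- pmax(areas, 0.5 * a0)   # guard against absurd draws at high sigma
  lipid_extent <- half_sep + 0.65
  r_pore <- if (is.null(spec$pore_radius)) NULL else spec$pore_radius / 10
  n_pore <- if (is.null(r_pore)) 0 else {
    max(1L, round(.BULK_WATER_NM3 * pi * r_pore^2 * spec$leaflet_separation))
  }

  meta <- NULL
  frames <- vector("list", spec$n_frames)
  for (fi in seq_len(spec$n_frames)) {
    lx <- sqrt(areas[fi])
    box <- c(lx, lx, spec$box_z)
    blocks <- vector("list", n_lip)
    meta_f <- if (is.null(meta)) vector("list", n_lip) else NULL
    for (i in seq_len(n_lip)) {
      sp <- species[i]
      up <- leaflet[i] == "upper"
      at <- c(frac_xy[i, ] * lx,
              z_mid + (if (up) half_sep else -half_sep) +
                stats::rnorm(1, 0, spec$p_jitter))
      psi <- stats::runif(1, 0, 2 * pi)
      spin <- stats::runif(1, 0, 2 * pi)
      parts <- if (sp == "OX3") c("OX3a", "OX3b") else sp
      xyz <- NULL
      for (frag in parts) {
        xf <- lipid_conformation(frag, tilt_deg = tilts[i], azimuth = psi,
                                 spin = spin, marker_z = marker_z,
                                 template = templates[[frag]])
        dest <- if (frag == "OX3b") at + c(0.45, 0, 0) else at
        xyz <- rbind(xyz, .orient_and_place(xf, up, dest))
      }
      blocks[[i]] <- xyz
      if (!is.null(meta_f)) {
        mi <- do.call(rbind, lapply(parts, function(frag) {
          .lipid_particle_rows(templates[[frag]], frag)
        }))
        mi$lipid_id <- i
        meta_f[[i]] <- mi
      }
    }
    wat <- .lattice_waters(comp$n_water, box, z_mid, lipid_extent)
    pore <- if (n_pore > 0) {
      .pore_waters(n_pore, r_pore, spec$leaflet_separation,
                   center = c(lx / 2, lx / 2, z_mid))
    } else NULL
    xyz <- do.call(rbind, blocks)
    if (!is.null(wat)) xyz <- rbind(xyz, wat$xyz)
    if (!is.null(pore)) xyz <- rbind(xyz, pore$xyz)
    for (k in 1:2) xyz[, k] <- xyz[, k] %% box[k]
    if (is.null(meta)) {
      meta <- do.call(rbind, meta_f)
      if (!is.null(wat)) meta <- rbind(meta, wat$meta)
      if (!is.null(pore)) meta <- rbind(meta, pore$meta)
      meta$resid <- .assign_resids(meta)
      rownames(meta) <- NULL
    }
    frames[[fi]] <- list(time = fi * spec$frame_dt, box = box, xyz = xyz)
  }

  traj <- bilayer_trajectory(meta, frames)
  core_truth <- if (is.null(r_pore)) 0 else {
    .BULK_WATER_KG_M3 * pi * r_pore^2 / a0
  }
  truth <- list(
    thickness = spec$leaflet_separation,
    apl = spec$apl_truth,
    apl_series = areas / npl,
    mean_scd = mean_scd_truth,
    core_water_density = core_truth,
    pore_diameter = if (is.null(spec$pore_radius)) NULL else 2 * spec$pore_radius,
    marker_abs_z = if (is.null(marker_z)) NULL else half_sep + marker_z,
    n_per_leaflet = npl,
    leaflet = stats::setNames(leaflet, seq_len(n_lip)),
    tilts = tilts
  )
  list(trajectory = traj, truth = truth)
}

# Bulk-packed water cylinder spanning the core: systematic (stratified) z so
# per-slab counts are near-deterministic, uniform random xy within the disk.
.pore_waters <- function(n, radius, height, center) {
  zs <- center[3] - height / 2 +
    (seq_len(n) - 0.5 + stats::runif(n, -0.3, 0.3)) * height / n
  rr <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  o <- cbind(center[1] + rr * cos(th), center[2] + rr * sin(th), zs)
  .water_block(o)
}

#' Generate a single frame with bent or linear oxidised-tail markers
#'
#' Emulates the two limiting conformations of the oxidised sn-2 tails: in
#' `straight` mode the polar aldehyde/peroxide markers sit halfway the
#' bilayer (where oxidation happens), in `bent` mode they sit just below the
#' phosphate planes (the equilibrated state, markers hydrogen-bonding toward
#' the water). The truth record carries the marker |z| so the density-profile
#' output can be checked against construction.
#'
#' @param spec A `synthetic_spec` whose composition includes an oxidised
#'   species; `spec$polar_bend` selects the mode.
#' @return List: `frame` (a `bilayer_frame`), `trajectory` (its one-frame
#'   trajectory) and `truth` (with `marker_abs_z`, nm from the midplane).
#' @export
gen_bent_tail_frame <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$composition$ox_species == "none") {
    stop("gen_bent_tail_frame needs a composition with an oxidised species")
  }
  one <- spec
  one$n_frames <- 1
  res <- gen_bilayer_trajectory(one)
  f <- res$trajectory$frames[[1]]
  frame <- bilayer_frame(res$trajectory$particles, f$xyz, f$box,
                         leaflet = res$truth$leaflet)
  list(frame = frame, trajectory = res$trajectory, truth = res$truth)
}
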