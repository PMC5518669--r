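# Trajectory analysis battery: area per lipid, phosphate-peak thickness,
# deuterium order parameters, mass density profiles, core water density,
# water-pore detection, and block-averaged error bars.

.AMU_NM3_TO_KG_M3 <- 1.66053906892  # 1 amu/nm^3 in kg/m^3

#' Scalar with an error estimate
#' @param value Numeric value.
#' @param error Non-negative error estimate.
#' @param method Label: `"block"`, `"bin-width"` or `"naive"`.
#' @param unit Optional unit string.
#' @export
scalar_with_error <- function(value, error, method, unit = NULL) {
  stopifnot(is.numeric(value), is.numeric(error), error >= 0)
  structure(list(value = value, error = error, method = method, unit = unit),
            class = "scalar_with_error")
}

#' @export
print.scalar_with_error <- function(x, ...) {
  cat(sprintf("%.6g +/- %.3g%s  [%s]\n", x$value, x$error,
              if (is.null(x$unit)) "" else paste0(" ", x$unit), x$method))
  invisible(x)
}

# Default equilibration cut: discard the first half of the trajectory.
.default_equil <- function(traj) {
  t <- frame_times(traj)
  if (length(t) == 1) return(-Inf)
  t[1] + (t[length(t)] - t[1]) / 2
}

#' Deuterium order parameter from bond-angle cosines
#'
#' S_CD = <(3 cos^2 theta - 1)/2> over the supplied cosines of the angle
#' between each C-D bond and the membrane normal. Equals 1 when every bond is
#' parallel to the normal (theta = 0) and -1/2 when every bond is
#' perpendicular (theta = 90 degrees); 0 for an isotropic orientation
#' distribution.
#'
#' @param cosines Numeric vector of cos(theta), each in `[-1, 1]`.
#' @return S_CD, in `[-0.5, 1]`.
#' @examples
#' scd_from_cosines(1)   #  1.0  (bond along the normal)
#' scd_from_cosines(0)   # -0.5  (bond perpendicular)
#' @export
scd_from_cosines <- function(cosines) {
  if (length(cosines) == 0) stop("empty cosine list")
  if (any(!is.finite(cosines)) || any(abs(cosines) > 1 + 1e-9)) {
    stop("cosines must lie in [-1, 1]")
  }
  cosines <- pmin(pmax(cosines, -1), 1)
  mean((3 * cosines^2 - 1) / 2)
}

#' Per-carbon and mean order parameter of the sn-1 chain
#'
#' Deuteriums are reconstructed geometrically on every sn-1 CD2 carbon (two
#' bonded heavy chain neighbours; the carbonyl and the terminal methyl have
#' no unique tetrahedral frame and are excluded), cos(theta) is taken against
#' the z axis, and S_CD is averaged over both C-D bonds, all lipids carrying
#' an sn-1 chain, and all post-equilibration frames.
#'
#' @param traj A `bilayer_trajectory`.
#' @param templates Named list of `lipid_template`s (default
#'   [default_templates()]).
#' @param equil_time Equilibration time in ps; frames at or before it are
#'   discarded. Default: half the trajectory.
#' @param include_c2 Include the C2 carbon adjacent to the ester carbonyl in
#'   the average (default TRUE: all CD2 carbons C2..C15 enter).
#' @param geometry A `deuterium_geometry`.
#' @return An `order_parameter_result`: `per_carbon` (named by chain carbon),
#'   `mean_scd`, `n_samples`.
#' @export
order_parameter <- function(traj, templates = default_templates(),
                            equil_time = NULL, include_c2 = TRUE,
                            geometry = deuterium_geometry()) {
  if (is.null(equil_time)) equil_time <- .default_equil(traj)
  frames <- .post_equil_frames(traj, equil_time)
  p <- traj$particles
  half <- geometry$hdh_angle / 2 * pi / 180

  # per species: matrix of global row indices, one row per lipid, columns in
  # sn-1 chain order
  chain_rows <- list()
  for (sp in names(templates)) {
    chain <- templates[[sp]]$sn1_chain
    if (length(chain) < 3) next
    ids <- unique(p$lipid_id[p$species == sp])
    ids <- ids[!is.na(ids)]
    if (!length(ids)) next
    rows <- t(vapply(ids, function(id) {
      ri <- which(p$lipid_id == id & p$species == sp)
      if (length(ri) != nrow(templates[[sp]]$particles)) {
        stop("lipid ", id, " (", sp, ") does not match its template layout")
      }
      ri[chain]
    }, integer(length(chain))))
    chain_rows[[sp]] <- rows
  }
  if (!length(chain_rows)) stop("trajectory contains no lipids with an sn-1 chain")

  n_chain <- ncol(chain_rows[[1]])
  sums <- numeric(n_chain - 2)   # interior chain positions 2..n-1
  counts <- numeric(n_chain - 2)
  for (f in frames) {
    for (rows in chain_rows) {
      acc <- .chain_scd_sums(f$xyz, rows, half, f$box)
      sums <- sums + acc$sum
      counts <- counts + acc$n
    }
  }
  keep <- counts > 0
  per_carbon <- stats::setNames(sums[keep] / counts[keep],
                                paste0("C", (2:(n_chain - 1))[keep]))
  if (!include_c2) per_carbon <- per_carbon[names(per_carbon) != "C2"]
  structure(list(per_carbon = per_carbon,
                 mean_scd = mean(per_carbon),
                 n_samples = sum(counts)),
            class = "order_parameter_result")
}

# Vectorised S_CD accumulation for one frame and one species.
# X: frame coordinates; rows: L x n matrix of particle rows along the chain.
# For interior position j the two heavy neighbours are chain positions j-1 and
# j+1 (the carbonyl end has extra ester/carbonyl neighbours and the methyl end
# only one, so both are outside the interior range). Chain displacement
# vectors take the periodic minimum image, so wrapped coordinates are safe.
# Returns per-position sums of the per-carbon S_CD (already averaged over the
# two C-D bonds) and counts.
.chain_scd_sums <- function(X, rows, half, box = NULL, tol = 1e-8) {
  L <- nrow(rows); n <- ncol(rows)
  co <- array(X[as.vector(rows), ], dim = c(L, n, 3))
  idx <- 2:(n - 1)
  a <- co[, idx - 1, , drop = FALSE] - co[, idx, , drop = FALSE]
  b <- co[, idx + 1, , drop = FALSE] - co[, idx, , drop = FALSE]
  if (!is.null(box)) {
    for (k in 1:3) {
      a[, , k] <- .pbc_wrap(a[, , k], box[k])
      b[, , k] <- .pbc_wrap(b[, , k], box[k])
    }
  }
  na <- sqrt(a[, , 1]^2 + a[, , 2]^2 + a[, , 3]^2)
  nb <- sqrt(b[, , 1]^2 + b[, , 2]^2 + b[, , 3]^2)
  ax <- a[, , 1] / na; ay <- a[, , 2] / na; az <- a[, , 3] / na
  bx <- b[, , 1] / nb; by <- b[, , 2] / nb; bz <- b[, , 3] / nb
  # v = a x b (normalised); u = -(a+b) (normalised)
  cx <- ay * bz - az * by
  cy <- az * bx - ax * bz
  cz <- ax * by - ay * bx
  ncr <- sqrt(cx^2 + cy^2 + cz^2)
  ux <- -(ax + bx); uy <- -(ay + by); uz <- -(az + bz)
  nu <- sqrt(ux^2 + uy^2 + uz^2)
  good <- ncr > tol & nu > tol
  c1 <- (uz / nu) * cos(half) + (cz / ncr) * sin(half)
  c2 <- (uz / nu) * cos(half) - (cz / ncr) * sin(half)
  s <- ((3 * c1^2 - 1) / 2 + (3 * c2^2 - 1) / 2) / 2
  s[!good] <- 0
  dim(s) <- c(L, length(idx)); dim(good) <- c(L, length(idx))
  list(sum = colSums(s), n = colSums(good))
}

#' Area per lipid with block-averaged error
#'
#' Per frame, the lateral area is box_x * box_y; the area per lipid is the
#' post-equilibration time mean divided by the number of lipids in one
#' leaflet (cholesterol counts as a lipid; an OX3 fragment pair counts once).
#'
#' @param traj A `bilayer_trajectory`.
#' @param n_per_leaflet Lipids per leaflet (>= 1).
#' @param equil_time Equilibration time, ps (default: half the trajectory).
#' @return A `scalar_with_error` in nm^2 (error by the block method; the
#'   naive standard error is used below 16 frames).
#' @export
area_per_lipid <- function(traj, n_per_leaflet, equil_time = NULL) {
  stopifnot(n_per_leaflet >= 1)
  if (is.null(equil_time)) equil_time <- .default_equil(traj)
  frames <- .post_equil_frames(traj, equil_time)
  apl <- vapply(frames, function(f) f$box[1] * f$box[2], numeric(1)) / n_per_leaflet
  if (length(apl) >= 16) {
    be <- block_error(apl)
    scalar_with_error(be$value, be$error, "block", "nm^2")
  } else {
    err <- if (length(apl) > 1) stats::sd(apl) / sqrt(length(apl)) else 0
    scalar_with_error(mean(apl), err, "naive", "nm^2")
  }
}

#' Mass density profile along the membrane normal
#'
#' Each frame's box is divided into `n_bins` z intervals (fractional binning,
#' so NPT box fluctuations are respected), recentred on the instantaneous
#' bilayer midplane (mean z of all phosphate P particles; box centre if there
#' are none). The mass of the selected particles is accumulated per bin over
#' the post-equilibration frames and divided by the accumulated bin volume,
#' so the profile integral recovers the selected mass exactly regardless of
#' box fluctuations. The bilayer must not wrap across the periodic z
#' boundary.
#'
#' @param traj A `bilayer_trajectory`.
#' @param selection Character vector of species/residue/particle names, or a
#'   predicate function on the particle table (see [phosphate_selection()],
#'   [water_selection()], [marker_selection()]).
#' @param n_bins Number of z bins (default 100).
#' @param equil_time Equilibration time, ps (default: half the trajectory).
#' @return A `density_profile`: data frame `bin_center` (nm, relative to the
#'   midplane) and `density` (kg m^-3), with attributes `bin_width`,
#'   `total_mass` (amu) and `n_frames`.
#' @export
density_profile <- function(traj, selection, n_bins = 100, equil_time = NULL) {
  if (is.null(equil_time)) equil_time <- .default_equil(traj)
  frames <- .post_equil_frames(traj, equil_time)
  p <- traj$particles
  sel <- .select_particles(p, selection)
  if (!any(sel)) {
    warning("empty selection: returning an all-zero profile", call. = FALSE)
  }
  masses <- p$mass[sel]
  pidx <- which(phosphate_selection(p))
  mass_bin <- numeric(n_bins)
  vol_sum <- 0
  mean_lz <- 0
  for (f in frames) {
    lz <- f$box[3]
    mid <- if (length(pidx)) mean(f$xyz[pidx, 3]) else lz / 2
    if (any(sel)) {
      zc <- f$xyz[sel, 3] - mid
      frac <- (zc / lz + 0.5) %% 1
      bin <- pmin(floor(frac * n_bins) + 1L, n_bins)
      mass_bin <- mass_bin + vapply(
        split(masses, factor(bin, levels = seq_len(n_bins))), sum, numeric(1))
    }
    vol_sum <- vol_sum + f$box[1] * f$box[2] * lz / n_bins
    mean_lz <- mean_lz + lz
  }
  nf <- length(frames)
  dens <- mass_bin / vol_sum * .AMU_NM3_TO_KG_M3
  mean_lz <- mean_lz / nf
  bw <- mean_lz / n_bins
  centers <- (seq_len(n_bins) - 0.5) * bw - mean_lz / 2
  structure(
    data.frame(bin_center = centers, density = unname(dens)),
    class = c("density_profile", "data.frame"),
    n_bins = n_bins, bin_width = bw, total_mass = sum(masses),
    n_frames = nf, mean_bin_volume = vol_sum / nf
  )
}

#' Bilayer thickness from the phosphate density profile
#'
#' The peak-to-peak distance between the density maxima on either side of
#' the midplane; ties within a side are broken toward larger |z|. The error
#' bar is one bin width.
#'
#' @param p_profile A `density_profile` of the phosphate particles.
#' @return A `scalar_with_error` in nm (method `"bin-width"`).
#' @export
bilayer_thickness <- function(p_profile) {
  z <- p_profile$bin_center
  d <- p_profile$density
  bw <- attr(p_profile, "bin_width")
  up <- z > 0
  if (max(d[up]) <= 0 || max(d[!up]) <= 0) {
    stop("cannot resolve two leaflet peaks (merged or missing leaflet)")
  }
  peak_of <- function(side) {
    zi <- z[side]; di <- d[side]
    cand <- which(di == max(di))
    zi[cand[which.max(abs(zi[cand]))]]
  }
  th <- peak_of(up) - peak_of(!up)
  if (th < 2 * bw) {
    stop("leaflet peaks not separated (merged-leaflet case)")
  }
  scalar_with_error(th, bw, "bin-width", "nm")
}

#' Water mass density in the membrane core
#'
#' Mean water mass density in the slab |z - z_mid| <= `half_width` around the
#' instantaneous phosphate midplane, averaged over post-equilibration frames.
#' Used as the polarity measure of the membrane interior.
#'
#' @param traj A `bilayer_trajectory`.
#' @param equil_time Equilibration time, ps (default: half the trajectory).
#' @param half_width Half width of the core slab, nm (default 0.5: the inner
#'   1 nm).
#' @return Density in kg m^-3.
#' @export
water_density_center <- function(traj, equil_time = NULL, half_width = 0.5) {
  if (is.null(equil_time)) equil_time <- .default_equil(traj)
  frames <- .post_equil_frames(traj, equil_time)
  p <- traj$particles
  wsel <- which(water_selection(p))
  if (!length(wsel)) stop("no water residues in trajectory")
  wmass <- p$mass[wsel]
  pidx <- which(phosphate_selection(p))
  dens <- vapply(frames, function(f) {
    mid <- if (length(pidx)) mean(f$xyz[pidx, 3]) else f$box[3] / 2
    zc <- .pbc_wrap(f$xyz[wsel, 3] - mid, f$box[3])
    m <- sum(wmass[abs(zc) <= half_width])
    m / (f$box[1] * f$box[2] * 2 * half_width)
  }, numeric(1))
  mean(dens) * .AMU_NM3_TO_KG_M3
}

#' Detect a transmembrane water pore
#'
#' Waters (O sites) lying between the two phosphate-peak planes are clustered
#' by single linkage at `link_cutoff` with periodic minimum-image distances.
#' A pore spans when one cluster reaches within `link_cutoff` of both planes.
#' The spanning cluster is sliced into `slab_width` z-slabs; each slab's
#' effective radius is r = sqrt(n * v_water / (pi * slab_width)) from its
#' water count n, with slab counts averaged over the spanning frames.
#'
#' @param traj A `bilayer_trajectory`.
#' @param equil_time Equilibration time, ps (default: half the trajectory).
#' @param link_cutoff Single-linkage cutoff, nm (default 0.35).
#' @param slab_width Slab thickness for the radius profile, nm (default 0.1).
#' @param v_water Volume per water molecule, nm^3 (default 0.030).
#' @return A `pore_report`: `spanning` (logical, NA if the membrane span is
#'   unresolvable), `diameter_max` / `diameter_min` in Angstrom (present only
#'   when spanning), `frame_of_onset` (ps), `n_frames_spanning`.
#' @export
detect_pore <- function(traj, equil_time = NULL, link_cutoff = 0.35,
                        slab_width = 0.1, v_water = 0.030) {
  if (is.null(equil_time)) equil_time <- .default_equil(traj)
  frames <- .post_equil_frames(traj, equil_time)
  th <- tryCatch(
    bilayer_thickness(density_profile(traj, phosphate_selection,
                                      equil_time = equil_time)),
    error = function(e) NULL
  )
  if (is.null(th)) {
    return(structure(list(spanning = NA, diameter_max = NULL,
                          diameter_min = NULL, frame_of_onset = NULL,
                          n_frames_spanning = 0L),
                     class = "pore_report"))
  }
  z_hi <- th$value / 2
  z_lo <- -z_hi
  p <- traj$particles
  osel <- which(p$name == "OW")
  pidx <- which(phosphate_selection(p))
  n_slab <- floor((z_hi - z_lo) / slab_width)
  edges <- z_lo + (0:n_slab) * slab_width
  slab_tot <- numeric(n_slab)
  onset <- NULL
  k_span <- 0L
  for (f in frames) {
    mid <- mean(f$xyz[pidx, 3])
    zc <- .pbc_wrap(f$xyz[osel, 3] - mid, f$box[3])
    core <- which(zc > z_lo & zc < z_hi)
    if (!length(core)) next
    xyzc <- f$xyz[osel[core], , drop = FALSE]
    cl <- .pbc_single_linkage(xyzc, f$box, link_cutoff)
    span_id <- NULL
    for (ci in unique(cl)) {
      zci <- zc[core[cl == ci]]
      if (min(zci) <= z_lo + link_cutoff && max(zci) >= z_hi - link_cutoff) {
        if (is.null(span_id) || sum(cl == ci) > sum(cl == span_id)) span_id <- ci
      }
    }
    if (is.null(span_id)) next
    k_span <- k_span + 1L
    if (is.null(onset)) onset <- f$time
    zs <- zc[core[cl == span_id]]
    bin <- findInterval(zs, edges, rightmost.closed = TRUE)
    bin <- bin[bin >= 1 & bin <= n_slab]
    slab_tot <- slab_tot + tabulate(bin, nbins = n_slab)
  }
  if (k_span == 0L) {
    return(structure(list(spanning = FALSE, diameter_max = NULL,
                          diameter_min = NULL, frame_of_onset = NULL,
                          n_frames_spanning = 0L),
                     class = "pore_report"))
  }
  r <- sqrt((slab_tot / k_span) * v_water / (pi * slab_width))  # nm
  structure(list(spanning = TRUE,
                 diameter_max = 2 * max(r) * 10,   # Angstrom
                 diameter_min = 2 * min(r) * 10,
                 frame_of_onset = onset,
                 n_frames_spanning = k_span),
            class = "pore_report")
}

#' @export
print.pore_report <- function(x, ...) {
  if (isTRUE(x$spanning)) {
    cat(sprintf(
      "<pore_report: spanning pore, diameter %.1f-%.1f A, onset t = %g ps (%d frames)>\n",
      x$diameter_min, x$diameter_max, x$frame_of_onset, x$n_frames_spanning))
  } else if (identical(x$spanning, FALSE)) {
    cat("<pore_report: no spanning pore>\n")
  } else {
    cat("<pore_report: membrane span unresolvable>\n")
  }
  invisible(x)
}

# Single-linkage clusters under periodic minimum-image distances.
.pbc_single_linkage <- function(xyz, box, cutoff) {
  n <- nrow(xyz)
  if (n == 1) return(1L)
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- .pbc_wrap(outer(xyz[, k], xyz[, k], "-"), box[k])
    d2 <- d2 + dk * dk
  }
  hc <- stats::hclust(stats::as.dist(sqrt(d2)), method = "single")
  stats::cutree(hc, h = cutoff)
}

#' Block-averaged error of the mean of a correlated series
#'
#' The series is blocked at geometrically increasing block sizes (powers of
#' two); at each size the squared standard error of the mean is estimated
#' from the block means. For correlated data the blocked SE rises toward a
#' plateau as blocks decorrelate. The plateau is extrapolated by fitting the
#' two-parameter closed form of the blocked variance of an AR(1)-correlated
#' series,
#'   s^2(b) = (sigma^2/n) * [ (1+phi)/(1-phi) - 2 phi (1-phi^b) / (b (1-phi)^2) ],
#' to the blocked-SE curve (weighted by block counts; sigma^2 enters
#' linearly, phi by one-dimensional optimisation), and reporting
#' sqrt(sigma^2 (1+phi) / ((1-phi) n)). If the fit degenerates the maximum
#' blocked SE is reported instead.
#'
#' @param series Numeric vector, length >= 16.
#' @return A `scalar_with_error`: the series mean with the plateau SE
#'   (method `"block"`).
#' @export
block_error <- function(series) {
  n <- length(series)
  if (n < 16) stop("block_error needs a series of length >= 16, got ", n)
  mu <- mean(series)
  if (stats::sd(series) == 0) return(scalar_with_error(mu, 0, "block"))
  bs <- 2^(0:floor(log2(n / 4)))
  m <- floor(n / bs)
  se2 <- vapply(seq_along(bs), function(i) {
    bm <- colMeans(matrix(series[seq_len(m[i] * bs[i])], nrow = bs[i]))
    stats::var(bm) / m[i]
  }, numeric(1))
  w <- pmax(m - 1, 1)
  g <- function(phi, b) {
    (1 + phi) / (1 - phi) - 2 * phi * (1 - phi^b) / (b * (1 - phi)^2)
  }
  sig2_for <- function(phi) {
    gb <- g(phi, bs) / n
    sum(w * gb * se2) / sum(w * gb^2)
  }
  obj <- function(phi) {
    s2 <- sig2_for(phi)
    sum(w * (se2 - s2 * g(phi, bs) / n)^2)
  }
  est <- tryCatch({
    phi <- stats::optimize(obj, c(0, 0.999))$minimum
    s2 <- sig2_for(phi)
    sqrt(s2 * (1 + phi) / ((1 - phi) * n))
  }, error = function(e) NA_real_)
  if (!is.finite(est) || est <= 0) est <- sqrt(max(se2))
  scalar_with_error(mu, est, "block")
}

#' Relative change versus a reference value, in percent
#' @param value New value.
#' @param reference Reference (non-zero) value.
#' @return 100 * (value - reference) / reference.
#' @export
relative_change <- function(value, reference) {
  if (reference == 0) stop("reference must be non-zero")
  100 * (value - reference) / reference
}

#' @export
print.order_parameter_result <- function(x, ...) {
  cat(sprintf("<order_parameter_result: mean S_CD = %.4f over %d carbons (%g samples)>\n",
              x$mean_scd, length(x$per_carbon), x$n_samples))
  print(round(x$per_carbon, 4))
  invisible(x)
}
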