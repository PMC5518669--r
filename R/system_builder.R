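# Composition bookkeeping and initial-configuration packing for 72-lipid
# POPC/cholesterol/oxidised-lipid bilayers with two outer water slabs.

#' Compose a bilayer system at given cholesterol and oxidation fractions
#'
#' Oxidised lipids replace POPC, so `ox_fraction` applies to the
#' non-cholesterol pool. Counts are rounded to the nearest integer (ties to
#' even) with POPC absorbing the remainder, and the realised fractions are
#' reported back alongside the requested ones. For OX3 the count is in
#' fragment PAIRS: each OX3a + OX3b pair is one lipid.
#'
#' @param n_lipids Total lipid count (default 72).
#' @param chol_fraction Cholesterol fraction of all lipids, in `[0, 1]`.
#' @param ox_fraction Oxidised fraction of the non-cholesterol pool, `[0, 1]`.
#' @param ox_species `"OX1"`, `"OX2"`, `"OX3"` or `"none"`.
#' @param n_water Number of water molecules (default 4000).
#' @param box Box edges in nm (default 5.5 x 5.5 x 11).
#' @return A `system_composition` with counts, realised fractions, water
#'   count and box.
#' @examples
#' make_composition(72, chol_fraction = 0.5)  # 36 POPC + 36 cholesterol
#' @export
make_composition <- function(n_lipids = 72, chol_fraction = 0,
                             ox_fraction = 0, ox_species = "none",
                             n_water = 4000, box = c(5.5, 5.5, 11.0)) {
  stopifnot(n_lipids >= 1, length(box) == 3, all(box > 0), n_water >= 0)
  if (chol_fraction < 0 || chol_fraction > 1) {
    stop("chol_fraction must be in [0, 1], got ", chol_fraction)
  }
  if (ox_fraction < 0 || ox_fraction > 1) {
    stop("ox_fraction must be in [0, 1], got ", ox_fraction)
  }
  if (!ox_species %in% c("none", "OX1", "OX2", "OX3")) {
    stop("ox_species must be one of none, OX1, OX2, OX3")
  }
  if (ox_fraction > 0 && ox_species == "none") {
    stop("ox_fraction > 0 requires an ox_species")
  }
  if (ox_fraction == 0) ox_species <- "none"
  n_chol <- round(n_lipids * chol_fraction)       # round half to even
  n_ox <- round((n_lipids - n_chol) * ox_fraction)
  n_popc <- n_lipids - n_chol - n_ox
  if (n_popc < 0) stop("fractions leave a negative POPC count")
  structure(list(
    n_lipids_total = as.integer(n_lipids),
    n_popc = as.integer(n_popc),
    n_chol = as.integer(n_chol),
    n_ox = as.integer(n_ox),
    ox_species = ox_species,
    n_water = as.integer(n_water),
    box = as.numeric(box),
    requested = c(chol_fraction = chol_fraction, ox_fraction = ox_fraction),
    realized = c(
      chol_fraction = n_chol / n_lipids,
      ox_fraction = if (n_lipids - n_chol > 0) n_ox / (n_lipids - n_chol) else 0
    )
  ), class = "system_composition")
}

#' @export
print.system_composition <- function(x, ...) {
  cat(sprintf(
    "<system_composition: %d lipids = %d POPC + %d CHOL + %d %s; %d waters; box %.2f x %.2f x %.2f nm>\n",
    x$n_lipids_total, x$n_popc, x$n_chol, x$n_ox,
    if (x$ox_species == "none") "OX" else x$ox_species,
    x$n_water, x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  realized: %.1f%% cholesterol, %.1f%% oxidized (of non-CHOL pool)\n",
              100 * x$realized[["chol_fraction"]],
              100 * x$realized[["ox_fraction"]]))
  invisible(x)
}

#' Enumerate a study grid of compositions
#'
#' Crosses oxidised species, oxidation fractions and cholesterol fractions
#' into deduplicated compositions (0% oxidation collapses across species).
#'
#' @param ox_species Character vector of oxidation species.
#' @param ox_fractions Numeric vector of oxidation fractions, `[0, 1]`.
#' @param chol_fractions Numeric vector of cholesterol fractions, `[0, 1]`.
#' @param ... Passed to [make_composition()] (`n_lipids`, `n_water`, `box`).
#' @return List of unique `system_composition` objects.
#' @export
enumerate_study_grid <- function(ox_species = c("OX1", "OX2", "OX3"),
                                 ox_fractions = c(0, 0.5, 1),
                                 chol_fractions = c(0, 0.5), ...) {
  grid <- expand.grid(ox = ox_species, f_ox = ox_fractions,
                      f_chol = chol_fractions, stringsAsFactors = FALSE)
  if (nrow(grid) == 0) return(list())
  comps <- lapply(seq_len(nrow(grid)), function(i) {
    make_composition(chol_fraction = grid$f_chol[i],
                     ox_fraction = grid$f_ox[i],
                     ox_species = if (grid$f_ox[i] > 0) grid$ox[i] else "none",
                     ...)
  })
  keys <- vapply(comps, function(cp) {
    paste(cp$n_popc, cp$n_chol, cp$n_ox, cp$ox_species, cp$n_water,
          paste(cp$box, collapse = ","), sep = "|")
  }, character(1))
  comps[!duplicated(keys)]
}

# Evaluate with a local RNG state so callers' streams are untouched and the
# same seed always gives the same result.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Minimum periodic (minimum-image) distance between two coordinate sets.
.min_pbc_dist <- function(a, b, box) {
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    dk <- .pbc_wrap(dk, box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(min(d2))
}

#' Pack an initial bilayer configuration
#'
#' Rejection-sampling placement: lipids are split evenly between the two
#' leaflets (head groups facing the water slabs), dropped at random lateral
#' positions and azimuths, and accepted only if every particle stays at least
#' `min_dist` from every particle of a DIFFERENT lipid (periodic
#' minimum-image distances; the OX3a/OX3b fragments of one lipid are exempt
#' from their mutual constraint). Waters fill the two outer slabs on a
#' jittered lattice at bulk packing. Deterministic for a fixed seed.
#'
#' @param comp A `system_composition`.
#' @param min_dist Inter-lipid minimum distance in Angstrom (default 2).
#' @param seed Integer RNG seed.
#' @param leaflet_half_sep Half distance between the phosphate planes, nm.
#' @param max_attempts Placement attempts per lipid before failing.
#' @return A `bilayer_frame` with leaflet assignment per lipid id.
#' @export
pack_initial_configuration <- function(comp, min_dist = 2.0, seed = 1,
                                       leaflet_half_sep = 1.9,
                                       max_attempts = 5000) {
  stopifnot(inherits(comp, "system_composition"), min_dist > 0)
  .with_seed(seed, .pack_impl(comp, min_dist / 10, leaflet_half_sep, max_attempts))
}

.pack_impl <- function(comp, min_dist_nm, half_sep, max_attempts) {
  box <- comp$box
  z_mid <- box[3] / 2
  templates <- default_templates()

  # lipid roster: species label per lipid (OX3 expands to the fragment pair)
  species <- c(rep("POPC", comp$n_popc), rep("CHOL", comp$n_chol),
               rep(comp$ox_species, comp$n_ox))
  species <- species[species != "none"]
  n_lip <- length(species)
  # alternate leaflets within each species for an even split
  leaflet <- unlist(lapply(table(factor(species, unique(species))), function(k) {
    rep_len(c("upper", "lower"), k)
  }), use.names = FALSE)

  placed_xyz <- NULL
  lipid_blocks <- vector("list", n_lip)
  for (i in seq_len(n_lip)) {
    sp <- species[i]
    up <- leaflet[i] == "upper"
    z_ref <- z_mid + (if (up) half_sep else -half_sep)
    parts <- if (sp == "OX3") c("OX3a", "OX3b") else sp
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      xy <- stats::runif(2) * box[1:2]
      psi <- stats::runif(1) * 2 * pi
      cand <- NULL
      cand_meta <- NULL
      for (frag in parts) {
        xyz <- lipid_conformation(frag, tilt_deg = 0, azimuth = psi,
                                  template = templates[[frag]])
        if (frag == "OX3b") {
          # short aldehyde fragment sits in the tail region of the same leaflet
          zb <- z_mid + (if (up) 0.6 else -0.6)
          xyz <- .orient_and_place(xyz, up, c(xy[1] + 0.45, xy[2], zb))
        } else {
          xyz <- .orient_and_place(xyz, up, c(xy, z_ref))
        }
        cand <- rbind(cand, xyz)
        cand_meta <- rbind(cand_meta, .lipid_particle_rows(templates[[frag]], frag))
      }
      if (is.null(placed_xyz) ||
          .min_pbc_dist(cand, placed_xyz, box) >= min_dist_nm) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf(
        "packing failed for lipid %d/%d (%s): %d attempts at %.1f A min distance; lipid density too high for box %.2f x %.2f nm",
        i, n_lip, sp, max_attempts, min_dist_nm * 10, box[1], box[2]))
    }
    placed_xyz <- rbind(placed_xyz, cand)
    cand_meta$lipid_id <- i
    lipid_blocks[[i]] <- list(meta = cand_meta, xyz = cand)
  }

  # waters: jittered lattice in the two slabs outside the lipid region
  lipid_extent <- half_sep + 0.65   # head groups reach ~0.55 nm past P
  wat <- .lattice_waters(comp$n_water, box, z_mid, lipid_extent)

  meta <- do.call(rbind, lapply(lipid_blocks, function(b) b$meta))
  xyz <- do.call(rbind, lapply(lipid_blocks, function(b) b$xyz))
  if (!is.null(wat)) {
    meta <- rbind(meta, wat$meta)
    xyz <- rbind(xyz, wat$xyz)
  }
  # wrap into [0, box)
  for (k in 1:3) xyz[, k] <- xyz[, k] %% box[k]
  meta$resid <- .assign_resids(meta)
  rownames(meta) <- NULL
  bilayer_frame(meta, xyz, box,
                leaflet = stats::setNames(leaflet, seq_len(n_lip)))
}

# mirror for the lower leaflet, then translate the reference to `at`
.orient_and_place <- function(xyz, upper, at) {
  if (!upper) xyz[, 3] <- -xyz[, 3]
  sweep(xyz, 2, at, "+")
}

.lipid_particle_rows <- function(template, species) {
  p <- template$particles
  data.frame(name = p$name, element = p$element, mass = p$mass,
             resname = toupper(species), resid = NA_integer_,
             lipid_id = NA_integer_, species = species,
             stringsAsFactors = FALSE)
}

# residue numbering: one resid per residue block; the OX3a/OX3b fragments of a
# lipid share the resid (the in-file encoding of the shared lipid ID)
.assign_resids <- function(meta) {
  key <- ifelse(is.na(meta$lipid_id),
                paste0("W", cumsum(meta$name == "OW")),
                paste0("L", meta$lipid_id))
  as.integer(factor(key, levels = unique(key)))
}

.lattice_waters <- function(n_water, box, z_mid, lipid_extent, jitter = 0.03) {
  if (n_water == 0) return(NULL)
  sites <- function(a) {
    nx <- max(1, floor(box[1] / a)); ny <- max(1, floor(box[2] / a))
    zs <- seq(a / 2, box[3] - a / 2, by = a)
    zs <- zs[abs(zs - z_mid) > lipid_extent]
    if (!length(zs)) return(NULL)
    expand.grid(x = (seq_len(nx) - 0.5) * box[1] / nx,
                y = (seq_len(ny) - 0.5) * box[2] / ny, z = zs)
  }
  a <- .BULK_WATER_NM3^(-1 / 3)
  grid <- sites(a)
  if (is.null(grid)) stop("no water slab volume outside the lipid region")
  while (nrow(grid) < n_water && a > 0.15) {
    # compress the lattice (denser than bulk) to fit the requested count
    a <- a * max((nrow(grid) / n_water)^(1 / 3), 0.96) * 0.99
    grid <- sites(a)
  }
  # fill from the box edges inward
  grid <- grid[order(-abs(grid$z - z_mid)), ]
  if (nrow(grid) < n_water) {
    stop(sprintf("water slabs hold only %d lattice sites, %d waters requested",
                 nrow(grid), n_water))
  }
  grid <- grid[seq_len(n_water), ]
  o_xyz <- as.matrix(grid) + matrix(stats::runif(3 * n_water, -jitter, jitter),
                                    ncol = 3)
  .water_block(o_xyz)
}

# Expand water oxygen positions into 3-site molecules with metadata.
.water_block <- function(o_xyz) {
  n <- nrow(o_xyz)
  off <- .water_site_offsets()
  xyz <- matrix(0, 3 * n, 3)
  for (s in 1:3) xyz[seq(s, 3 * n, by = 3), ] <- sweep(o_xyz, 2, off[s, ], "+")
  meta <- data.frame(
    name = rep(c("OW", "HW1", "HW2"), n),
    element = rep(c("O", "H", "H"), n),
    mass = rep(c(15.999, 1.008, 1.008), n),
    resname = "SOL", resid = NA_integer_, lipid_id = NA_integer_,
    species = "SOL", stringsAsFactors = FALSE
  )
  list(meta = meta, xyz = xyz)
}
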