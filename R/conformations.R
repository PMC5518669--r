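# Idealised single-lipid conformations used for initial packing and for the
# synthetic-bilayer generator. These are geometric stand-ins (rigid all-trans
# chains, compact head groups), not energy-minimised structures: packing only
# needs excluded volume, and the order-parameter ground truth needs an exact
# tetrahedral zig-zag.

.CC_BOND <- 0.154       # nm, C-C bond length
.TETRA_DEG <- 109.47    # ideal sp3 backbone angle
.BULK_WATER_NM3 <- 33.4 # water molecules per nm^3 at ambient conditions

#' All-trans zig-zag chain positions
#'
#' Generates `n` positions of an ideal tetrahedral zig-zag whose axis is the
#' local -z direction, first atom at the origin, zig-zag plane = xz.
#'
#' @param n Number of chain atoms.
#' @param bond Bond length in nm.
#' @param backbone_deg Backbone (C-C-C) angle in degrees.
#' @return `n` x 3 matrix, nm.
#' @export
zigzag_chain <- function(n, bond = .CC_BOND, backbone_deg = .TETRA_DEG) {
  stopifnot(n >= 1)
  # consecutive bond vectors (+s,0,-c) / (-s,0,-c) give backbone angle
  # acos(c^2 - s^2); for 109.47 deg, c = 1/sqrt(3).
  cth <- sqrt((1 - cos(backbone_deg * pi / 180)) / 2)
  sth <- sqrt(1 - cth^2)
  dz <- -bond * cth
  dx <- bond * sth
  x <- rep(c(0, dx), length.out = n)
  z <- (seq_len(n) - 1) * dz
  cbind(x = x, y = 0, z = z)
}

.rot_z <- function(psi) {
  c <- cos(psi); s <- sin(psi)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

.rot_y <- function(th) {
  c <- cos(th); s <- sin(th)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

# Rotation taking the local -z chain axis to a direction tilted `tilt` from -z:
# first spin the chain about its own axis (`spin`), then tilt about y, then set
# the tilt direction in the xy plane (`azimuth`). The spin is what rotationally
# averages the C-D directions about the chain axis; the outer azimuth leaves
# z-components untouched.
.tilt_rotation <- function(tilt_deg, azimuth, spin = 0) {
  .rot_z(azimuth) %*% .rot_y(tilt_deg * pi / 180) %*% .rot_z(spin)
}

#' Idealised coordinates for one lipid, reference particle at the origin
#'
#' Builds a geometric conformation of `species` in a leaflet-local frame:
#' head group above the reference particle (the phosphate P, or the hydroxyl
#' O for cholesterol, or the aldehyde carbon for the OX3b fragment), acyl
#' chains descending toward -z. The sn-1 palmitoyl chain is an exact
#' tetrahedral zig-zag whose axis is tilted `tilt_deg` from -z at the given
#' azimuth, which fixes the order-parameter ground truth. For the oxidised
#' species the polar marker atoms can be pinned at a controlled depth
#' `marker_z` (nm, relative to the reference particle; negative = toward the
#' bilayer core) to emulate the linear (markers deep) versus bent (markers
#' near the phosphate plane) tail conformations.
#'
#' @param species One of `template_species()`.
#' @param tilt_deg sn-1 chain tilt from the bilayer normal, degrees.
#' @param azimuth Azimuthal direction of the tilt, radians.
#' @param spin Rotation of the chain about its own axis, radians; a uniform
#'   spin realises the rotational average that underlies the S_CD closed form.
#' @param marker_z Optional depth (nm, relative z) at which polar marker
#'   atoms are pinned; NULL leaves them at their chain position.
#' @param template Optional pre-built template (avoids rebuilding).
#' @return n_particles x 3 coordinate matrix (nm) in template order.
#' @export
lipid_conformation <- function(species, tilt_deg = 0, azimuth = 0, spin = 0,
                               marker_z = NULL, template = NULL) {
  if (is.null(template)) template <- build_template(species)
  n <- nrow(template$particles)
  xyz <- matrix(0, n, 3)
  nm <- template$particles$name

  place <- function(name, v) xyz[match(name, nm), ] <<- v

  if (species %in% c("POPC", "OX1", "OX2", "OX3a")) {
    # head group: compact cluster above P (reference, at origin)
    place("P",   c(0, 0, 0))
    place("OP1", c(0.06, 0.10, 0.08))
    place("OP2", c(-0.13, 0.05, 0.05))
    place("OP3", c(0.05, -0.13, 0.05))
    place("OP4", c(0.00, 0.06, -0.13))
    place("CA1", c(0.10, 0.16, 0.18))
    place("CA2", c(0.12, 0.20, 0.32))
    place("NTM", c(0.08, 0.14, 0.45))
    place("CN1", c(0.20, 0.10, 0.52))
    place("CN2", c(-0.04, 0.06, 0.52))
    place("CN3", c(0.06, 0.28, 0.52))
    place("CG3", c(0.02, 0.04, -0.27))
    place("CG2", c(0.10, -0.04, -0.36))
    place("CG1", c(0.22, 0.02, -0.44))
    place("OE1", c(0.26, -0.04, -0.56))
    # sn-1 palmitoyl: exact zig-zag, tilted; C1A..C16A
    sn1 <- template$sn1_chain
    R <- .tilt_rotation(tilt_deg, azimuth, spin)
    chain <- zigzag_chain(length(sn1)) %*% t(R)
    origin1 <- c(0.26, -0.04, -0.66)
    xyz[sn1, ] <- sweep(chain, 2, origin1, "+")
    place("OD1", xyz[sn1[1], ] + c(0.12, 0.05, 0.02))
    # sn-2: straight zig-zag offset laterally
    sn2_names <- nm[grepl("B$", nm)]
    sn2_carbons <- nm[grepl("^C[0-9]+B$", nm)]
    place("OE2", c(-0.16, 0.02, -0.40))
    chain2 <- zigzag_chain(length(sn2_carbons))
    origin2 <- c(-0.20, 0.10, -0.52)
    xyz[match(sn2_carbons, nm), ] <- sweep(chain2, 2, origin2, "+")
    place("OD2", xyz[match("C1B", nm), ] + c(-0.12, 0.05, 0.02))
    if (species %in% c("OX2", "OX3a")) {
      place("OA9", xyz[match("C9B", nm), ] + c(-0.12, 0.05, 0.02))
    }
    if (species == "OX1") {
      c9 <- xyz[match("C9B", nm), ]
      place("OA",  c9 + c(-0.12, 0.06, 0.00))
      place("OB",  c9 + c(-0.22, 0.12, 0.06))
      place("HOP", c9 + c(-0.28, 0.16, 0.12))
    }
    if (!is.null(marker_z) && length(template$polar_marker_indices)) {
      mk <- template$polar_marker_indices
      anchor <- if (species == "OX1") match("C9B", nm) else match("C9B", nm)
      # pin the marker-bearing group at the requested depth, small spread
      off <- xyz[mk, , drop = FALSE]
      off <- sweep(off, 2, xyz[anchor, ], "-")
      base <- c(xyz[anchor, 1], xyz[anchor, 2], marker_z)
      xyz[mk, ] <- sweep(off, 2, base, "+")
      xyz[anchor, 3] <- marker_z
    }
  } else if (species == "CHOL") {
    # hydroxyl at top (O3 reference at origin), fused-ring carbons and tail
    # approximated by a descending zig-zag in sterol order
    place("HO", c(0.04, 0.02, 0.10))
    place("O3", c(0, 0, 0))
    order_c <- c("C3", "C2", "C1", "C10", "C5", "C4", "C19", "C6", "C7", "C8",
                 "C9", "C11", "C12", "C13", "C18", "C14", "C15", "C16", "C17",
                 "C20", "C21", "C22", "C23", "C24", "C25", "C26", "C27")
    chain <- zigzag_chain(length(order_c))
    # compress: fused rings are shorter than an extended chain
    chain[, 3] <- chain[, 3] * 0.75
    xyz[match(order_c, nm), ] <- sweep(chain, 2, c(0.05, 0.03, -0.10), "+")
  } else if (species == "OX3b") {
    # nonanal, reference C1N (aldehyde end) at origin
    order_c <- c("C1N", paste0("C", 2:8, "N"), "C9N")
    chain <- zigzag_chain(length(order_c))
    xyz[match(order_c, nm), ] <- chain
    place("OA1", xyz[match("C1N", nm), ] + c(-0.12, 0.05, 0.02))
    if (!is.null(marker_z)) {
      # shift whole fragment so the aldehyde O sits at the requested depth
      xyz[, 3] <- xyz[, 3] + (marker_z - xyz[match("OA1", nm), 3])
    }
  } else {
    stop("no conformation rule for species ", species)
  }
  xyz
}

# Rigid 3-site water (O, H, H): OH 0.09572 nm, HOH 104.52 deg, O at origin.
.water_site_offsets <- function() {
  roh <- 0.09572
  half <- 104.52 / 2 * pi / 180
  rbind(
    O  = c(0, 0, 0),
    H1 = c(roh * sin(half), 0, roh * cos(half)),
    H2 = c(-roh * sin(half), 0, roh * cos(half))
  )
}
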