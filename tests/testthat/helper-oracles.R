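# Independent oracles and small fixture builders used across the suite.

# O(N^2) brute-force minimum inter-lipid particle distance under periodic
# minimum-image convention. Deliberately naive: the reference for the packer.
brute_min_interlipid_dist <- function(frame) {
  p <- frame$particles
  lip <- which(!is.na(p$lipid_id))
  xyz <- frame$xyz[lip, , drop = FALSE]
  id <- p$lipid_id[lip]
  box <- frame$box
  n <- length(lip)
  best <- Inf
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    j <- j[id[j] != id[i]]
    if (!length(j)) next
    d2 <- 0
    for (k in 1:3) {
      dk <- xyz[j, k] - xyz[i, k]
      dk <- dk - box[k] * round(dk / box[k])
      d2 <- d2 + dk^2
    }
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# Unwrap a chain of coordinates that may be wrapped across the periodic
# boundary: successive displacements take the minimum image.
unwrap_chain <- function(coords, box) {
  out <- coords
  for (i in 2:nrow(coords)) {
    d <- coords[i, ] - out[i - 1, ]
    d <- d - box * round(d / box)
    out[i, ] <- out[i - 1, ] + d
  }
  out
}

# Brute-force mean S_CD of one lipid's sn-1 chain from raw coordinates,
# via reconstruct_deuteriums (the per-template reference path).
brute_chain_scd <- function(coords, template, geometry = deuterium_geometry()) {
  dd <- reconstruct_deuteriums(coords, template, geometry)
  vapply(dd, function(e) {
    (scd_from_cosines(e$d1[3]) + scd_from_cosines(e$d2[3])) / 2
  }, numeric(1))
}

# Monte-Carlo spread of the per-chain S_CD observable at fixed tilt with
# uniform spin about the chain axis (used only to size tolerances).
mc_chain_scd_sd <- function(tilt_deg, n = 2e5, seed = 99) {
  a <- tilt_deg * pi / 180
  half <- 109.47 / 2 * pi / 180
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  psi <- stats::runif(n, 0, 2 * pi)
  d1 <- cos(half) * (-cos(psi) * sin(a)) + sin(half) * (sin(psi) * sin(a))
  d2 <- cos(half) * (-cos(psi) * sin(a)) - sin(half) * (sin(psi) * sin(a))
  stats::sd(((3 * d1^2 - 1) / 2 + (3 * d2^2 - 1) / 2) / 2)
}

# Minimal hand-built trajectory: particle table rows are given directly.
make_manual_traj <- function(name, resname, mass, lipid_id, xyz, box,
                             times = 100) {
  p <- data.frame(
    name = name, element = substr(name, 1, 1), mass = mass,
    resname = resname, resid = ifelse(is.na(lipid_id), 0L, lipid_id),
    lipid_id = lipid_id,
    species = ifelse(resname == "SOL", "SOL", resname),
    stringsAsFactors = FALSE
  )
  frames <- lapply(times, function(t) list(time = t, box = box, xyz = xyz))
  bilayer_trajectory(p, frames)
}

# A trajectory with only box areas (no meaningful particles): enough for
# area_per_lipid, which reads boxes only.
make_area_traj <- function(areas, lz = 10) {
  p <- data.frame(name = "P", element = "P", mass = 30.974, resname = "POPC",
                  resid = 1L, lipid_id = 1L, species = "POPC",
                  stringsAsFactors = FALSE)
  frames <- lapply(seq_along(areas), function(i) {
    list(time = i * 100, box = c(sqrt(areas[i]), sqrt(areas[i]), lz),
         xyz = matrix(c(1, 1, lz / 2), 1, 3))
  })
  bilayer_trajectory(p, frames)
}
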