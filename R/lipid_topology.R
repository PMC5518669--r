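# United-atom lipid templates and deuterium reconstruction.
#
# Species covered: POPC, cholesterol (CHOL), and three peroxidation products of
# POPC: OX1 (sn-2 hydroperoxide), OX2 (sn-2 chain-cleaved to the 9-aldehyde,
# small fragment discarded), OX3 = OX3a (identical phospholipid aldehyde) +
# OX3b (the complementary short-chain aldehyde, nonanal), bookkept as ONE lipid.

# Atomic masses (amu). United-atom particle mass = heavy atom + merged H.
.OX_ELEMENT_MASS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974)

.ua_mass <- function(element, n_h) {
  unname(.OX_ELEMENT_MASS[element] + n_h * .OX_ELEMENT_MASS[["H"]])
}

.particle_df <- function(name, element, n_h) {
  data.frame(
    name = name, element = element, n_merged_h = as.integer(n_h),
    mass = .ua_mass(element, n_h), stringsAsFactors = FALSE
  )
}

#' Species labels known to the topology module
#'
#' `OX3` is represented in files and templates as the fragment pair
#' (`OX3a`, `OX3b`); the pair counts as one lipid in all per-lipid accounting.
#' @return Character vector of template species labels.
#' @export
template_species <- function() c("POPC", "CHOL", "OX1", "OX2", "OX3a", "OX3b")

# Shared head group + glycerol + sn-1 palmitoyl block (particles 1..32 of POPC).
# Naming convention (stable across species): CN* choline methyls, NTM quaternary
# N, CA* choline CH2, OP* phosphate oxygens, CG* glycerol, OE*/OD* ester/carbonyl
# oxygens, C<k>A palmitoyl (sn-1) carbons, C<k>B sn-2 carbons.
.popc_head_sn1 <- function() {
  rbind(
    .particle_df("CN1", "C", 3), # 1  N-methyl
    .particle_df("CN2", "C", 3), # 2
    .particle_df("CN3", "C", 3), # 3
    .particle_df("NTM", "N", 0), # 4  quaternary N
    .particle_df("CA2", "C", 2), # 5  N-CH2
    .particle_df("CA1", "C", 2), # 6  CH2-O
    .particle_df("OP1", "O", 0), # 7  choline ester O
    .particle_df("P",   "P", 0), # 8  phosphorus
    .particle_df("OP2", "O", 0), # 9  free phosphate O
    .particle_df("OP3", "O", 0), # 10 free phosphate O
    .particle_df("OP4", "O", 0), # 11 glycerol ester O
    .particle_df("CG3", "C", 2), # 12 glycerol C3
    .particle_df("CG2", "C", 1), # 13 glycerol C2 (sn-2 attachment)
    .particle_df("CG1", "C", 2), # 14 glycerol C1 (sn-1 attachment)
    .particle_df("OE1", "O", 0), # 15 sn-1 ester O
    .particle_df("C1A", "C", 0), # 16 palmitoyl carbonyl C
    .particle_df("OD1", "O", 0), # 17 palmitoyl carbonyl =O
    do.call(rbind, lapply(2:15, function(k) .particle_df(sprintf("C%dA", k), "C", 2))), # 18..31
    .particle_df("C16A", "C", 3) # 32 terminal CH3
  )
}

.popc_head_sn1_bonds <- function() {
  rbind(
    c(1, 4), c(2, 4), c(3, 4), c(4, 5), c(5, 6), c(6, 7), c(7, 8),
    c(8, 9), c(8, 10), c(8, 11), c(11, 12), c(12, 13), c(13, 14),
    c(14, 15), c(15, 16), c(16, 17),
    cbind(c(16, 18:31), c(18:31, 32)) # C1A-C2A-...-C16A
  )
}

.template_obj <- function(species, particles, bonds, sn1_chain, phosphate_index,
                          polar_marker_indices) {
  structure(
    list(
      species = species,
      particles = particles,
      bonds = bonds,
      sn1_chain = sn1_chain,
      phosphate_index = phosphate_index,
      polar_marker_indices = polar_marker_indices
    ),
    class = "lipid_template"
  )
}

#' Build the united-atom template for a lipid species
#'
#' United-atom reduction: each aliphatic carbon and its bonded hydrogens form
#' one particle (`n_merged_h` implicit hydrogens); polar hydrogens (hydroxyl,
#' hydroperoxide) are retained as explicit particles. POPC (134 atoms) reduces
#' to 52 particles.
#'
#' @param species One of `template_species()`: `"POPC"`, `"CHOL"`, `"OX1"`,
#'   `"OX2"`, `"OX3a"`, `"OX3b"`. Oxidation species: OX1 carries a
#'   hydroperoxide (-OOH) on the sn-2 chain, OX2/OX3a carry the sn-2 aldehyde
#'   from oxidative chain cleavage, OX3b is the complementary short-chain
#'   aldehyde (nonanal).
#' @return A `lipid_template`: list with `species`, `particles`
#'   (data frame: name, element, n_merged_h, mass), `bonds` (two-column index
#'   matrix), `sn1_chain` (ordered palmitoyl carbon indices used for S_CD),
#'   `phosphate_index` (NA for CHOL/OX3b), `polar_marker_indices` (peroxide or
#'   aldehyde oxygens; empty for POPC/CHOL).
#' @examples
#' t <- build_template("POPC")
#' nrow(t$particles)                        # 52 united-atom particles
#' sum(1 + t$particles$n_merged_h)          # 134 implied all-atom count
#' @export
build_template <- function(species) {
  if (!is.character(species) || length(species) != 1 ||
      !(species %in% template_species())) {
    stop("unknown lipid species '", paste(species, collapse = ","),
         "'; expected one of: ", paste(template_species(), collapse = ", "),
         " (request OX3 as the pair OX3a + OX3b)", call. = FALSE)
  }
  switch(species,
    POPC = .build_popc(),
    CHOL = .build_chol(),
    OX1  = .build_ox1(),
    OX2  = .build_ox2("OX2"),
    OX3a = .build_ox2("OX3a"),
    OX3b = .build_ox3b()
  )
}

.build_popc <- function() {
  particles <- rbind(
    .popc_head_sn1(),
    .particle_df("OE2", "O", 0),  # 33 sn-2 ester O
    .particle_df("C1B", "C", 0),  # 34 oleoyl carbonyl C
    .particle_df("OD2", "O", 0),  # 35 oleoyl carbonyl =O
    do.call(rbind, lapply(2:8, function(k) .particle_df(sprintf("C%dB", k), "C", 2))),  # 36..42
    .particle_df("C9B",  "C", 1), # 43 =CH
    .particle_df("C10B", "C", 1), # 44 =CH
    do.call(rbind, lapply(11:17, function(k) .particle_df(sprintf("C%dB", k), "C", 2))), # 45..51
    .particle_df("C18B", "C", 3)  # 52 terminal CH3
  )
  bonds <- rbind(
    .popc_head_sn1_bonds(),
    c(13, 33), c(33, 34), c(34, 35),
    cbind(c(34, 36:51), c(36:51, 52)) # C1B-...-C18B
  )
  .template_obj("POPC", particles, bonds,
                sn1_chain = c(16L, 18:32), phosphate_index = 8L,
                polar_marker_indices = integer(0))
}

.build_chol <- function() {
  # Standard sterol numbering; rings fused A(1,2,3,4,5,10) B(5,6,7,8,9,10)
  # C(8,9,11,12,13,14) D(13,14,15,16,17); C19/C18 angular methyls; iso-octyl
  # tail C20..C27. Hydroxyl H retained as an explicit polar particle.
  particles <- rbind(
    .particle_df("HO",  "H", 0), # 1  hydroxyl H (polar, retained)
    .particle_df("O3",  "O", 0), # 2
    .particle_df("C3",  "C", 1), # 3
    .particle_df("C2",  "C", 2), # 4
    .particle_df("C1",  "C", 2), # 5
    .particle_df("C10", "C", 0), # 6
    .particle_df("C19", "C", 3), # 7
    .particle_df("C5",  "C", 0), # 8
    .particle_df("C4",  "C", 2), # 9
    .particle_df("C6",  "C", 1), # 10 (=CH)
    .particle_df("C7",  "C", 2), # 11
    .particle_df("C8",  "C", 1), # 12
    .particle_df("C9",  "C", 1), # 13
    .particle_df("C11", "C", 2), # 14
    .particle_df("C12", "C", 2), # 15
    .particle_df("C13", "C", 0), # 16
    .particle_df("C18", "C", 3), # 17
    .particle_df("C14", "C", 1), # 18
    .particle_df("C15", "C", 2), # 19
    .particle_df("C16", "C", 2), # 20
    .particle_df("C17", "C", 1), # 21
    .particle_df("C20", "C", 1), # 22
    .particle_df("C21", "C", 3), # 23
    .particle_df("C22", "C", 2), # 24
    .particle_df("C23", "C", 2), # 25
    .particle_df("C24", "C", 2), # 26
    .particle_df("C25", "C", 1), # 27
    .particle_df("C26", "C", 3), # 28
    .particle_df("C27", "C", 3)  # 29
  )
  bonds <- rbind(
    c(1, 2), c(2, 3),
    c(3, 4), c(4, 5), c(5, 6), c(6, 8), c(8, 9), c(9, 3),   # ring A
    c(6, 7),                                                # C10-C19
    c(8, 10), c(10, 11), c(11, 12), c(12, 13), c(13, 6),    # ring B (C5=C6)
    c(13, 14), c(14, 15), c(15, 16), c(16, 18), c(18, 12),  # ring C
    c(16, 17),                                              # C13-C18
    c(18, 19), c(19, 20), c(20, 21), c(21, 16),             # ring D
    c(21, 22), c(22, 23), c(22, 24), c(24, 25), c(25, 26),
    c(26, 27), c(27, 28), c(27, 29)                         # tail
  )
  .template_obj("CHOL", particles, bonds,
                sn1_chain = integer(0), phosphate_index = NA_integer_,
                polar_marker_indices = integer(0))
}

.build_ox1 <- function() {
  # POPC with a hydroperoxide at sn-2 C9 and the conjugated trans double bond
  # shifted to C10=C11. Markers: the two peroxide oxygens.
  p <- .build_popc()
  particles <- p$particles
  particles[43, ] <- .particle_df("C9B",  "C", 1) # sp3 CH bearing -OOH
  particles[44, ] <- .particle_df("C10B", "C", 1) # =CH
  particles[45, ] <- .particle_df("C11B", "C", 1) # =CH (was CH2)
  particles <- rbind(
    particles,
    .particle_df("OA",  "O", 0), # 53 peroxide O (C-O)
    .particle_df("OB",  "O", 0), # 54 peroxide O (O-H)
    .particle_df("HOP", "H", 0)  # 55 hydroperoxide H (polar, retained)
  )
  bonds <- rbind(p$bonds, c(43, 53), c(53, 54), c(54, 55))
  .template_obj("OX1", particles, bonds,
                sn1_chain = p$sn1_chain, phosphate_index = 8L,
                polar_marker_indices = c(53L, 54L))
}

.build_ox2 <- function(species) {
  # sn-2 chain oxidatively cleaved at the 9,10 double bond: 9-oxononanoyl
  # (aldehyde at C9). OX3a is chemically identical; its complementary fragment
  # OX3b (nonanal) is a separate residue sharing the lipid ID.
  particles <- rbind(
    .popc_head_sn1(),
    .particle_df("OE2", "O", 0), # 33
    .particle_df("C1B", "C", 0), # 34
    .particle_df("OD2", "O", 0), # 35
    do.call(rbind, lapply(2:8, function(k) .particle_df(sprintf("C%dB", k), "C", 2))), # 36..42
    .particle_df("C9B", "C", 1), # 43 aldehyde C (CHO)
    .particle_df("OA9", "O", 0)  # 44 aldehyde O (marker)
  )
  bonds <- rbind(
    .popc_head_sn1_bonds(),
    c(13, 33), c(33, 34), c(34, 35),
    cbind(c(34, 36:42), c(36:42, 43)),
    c(43, 44)
  )
  .template_obj(species, particles, bonds,
                sn1_chain = c(16L, 18:32), phosphate_index = 8L,
                polar_marker_indices = 44L)
}

.build_ox3b <- function() {
  # Nonanal: CHO-(CH2)7-CH3, the short-chain aldehyde released by cleavage.
  particles <- rbind(
    .particle_df("C1N", "C", 1), # 1 aldehyde C
    .particle_df("OA1", "O", 0), # 2 aldehyde O (marker)
    do.call(rbind, lapply(2:8, function(k) .particle_df(sprintf("C%dN", k), "C", 2))), # 3..9
    .particle_df("C9N", "C", 3)  # 10 terminal CH3
  )
  bonds <- rbind(c(1, 2), cbind(c(1, 3:8), c(3:8, 9)), c(9, 10))
  .template_obj("OX3b", particles, bonds,
                sn1_chain = integer(0), phosphate_index = NA_integer_,
                polar_marker_indices = 2L)
}

#' All templates keyed by species
#' @return Named list of `lipid_template` objects for `template_species()`.
#' @export
default_templates <- function() {
  sp <- template_species()
  stats::setNames(lapply(sp, build_template), sp)
}

#' Total united-atom mass of a template (amu)
#' @param template A `lipid_template`.
#' @export
template_mass <- function(template) sum(template$particles$mass)

#' @export
print.lipid_template <- function(x, ...) {
  cat(sprintf("<lipid_template %s: %d particles, %d bonds, mass %.3f amu>\n",
              x$species, nrow(x$particles), nrow(x$bonds), template_mass(x)))
  if (length(x$sn1_chain)) {
    cat("  sn-1 chain:", paste(x$particles$name[x$sn1_chain], collapse = "-"), "\n")
  }
  if (length(x$polar_marker_indices)) {
    cat("  polar markers:",
        paste(x$particles$name[x$polar_marker_indices], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a template to a plain-text particle table
#'
#' One row per particle: index, name, element, n_merged_h, mass (amu),
#' written as tab-separated values with a commented header.
#' @param template A `lipid_template`.
#' @param path Output file path.
#' @export
write_template_table <- function(template, path) {
  df <- cbind(index = seq_len(nrow(template$particles)), template$particles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# united-atom template %s; mass in amu", template$species), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Deuterium reconstruction geometry
#'
#' Implicit deuteriums are re-attached to chain carbons with ideal sp3
#' (tetrahedral) geometry: D-C-D angle 109.47 degrees. Only the C-D
#' *direction* enters the order parameter, so `bond_length` has no downstream
#' effect; it is kept for completeness.
#'
#' @param bond_length C-D distance in nm (default 0.1).
#' @param hdh_angle D-C-D angle in degrees (default tetrahedral 109.47).
#' @export
deuterium_geometry <- function(bond_length = 0.1, hdh_angle = 109.47) {
  stopifnot(bond_length > 0, hdh_angle > 0, hdh_angle < 180)
  structure(list(bond_length = bond_length, hdh_angle = hdh_angle),
            class = "deuterium_geometry")
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Reconstruct deuterium directions on sn-1 chain carbons
#'
#' For each sn-1 carbon with exactly two bonded heavy neighbours A and B
#' (i.e. the CD2 methylenes; the carbonyl and terminal methyl are excluded),
#' the two C-D unit vectors are placed in the plane bisecting A-C-B:
#' with a, b the unit vectors C->A, C->B, u = -(a+b)/|a+b|, v = (a x b)/|a x b|,
#' D1,2 = u cos(angle/2) +/- v sin(angle/2). Both make equal angles with a and b
#' and span the D-C-D angle exactly.
#'
#' @param coords Numeric matrix (n_particles x 3), nm, in template order.
#' @param template A `lipid_template` with a non-empty `sn1_chain`.
#' @param geometry A `deuterium_geometry`.
#' @param tol Collinearity tolerance on |a x b|; degenerate carbons are
#'   skipped with a warning.
#' @return List of entries `list(carbon = index, d1 = , d2 = )` with unit
#'   3-vectors; skipped carbon indices in attribute `"skipped"`.
#' @export
reconstruct_deuteriums <- function(coords, template,
                                   geometry = deuterium_geometry(),
                                   tol = 1e-8) {
  stopifnot(is.matrix(coords), ncol(coords) == 3,
            nrow(coords) == nrow(template$particles))
  chain <- template$sn1_chain
  if (length(chain) < 3) {
    stop("template '", template$species, "' has no usable sn-1 chain")
  }
  heavy <- template$particles$element != "H"
  half <- geometry$hdh_angle / 2 * pi / 180
  out <- list()
  skipped <- integer(0)
  for (ci in chain) {
    nb <- .heavy_neighbours(ci, template$bonds, heavy)
    if (length(nb) != 2) next # carbonyl (3 heavy nb) and terminal CH3 (1)
    a <- .unit(coords[nb[1], ] - coords[ci, ])
    b <- .unit(coords[nb[2], ] - coords[ci, ])
    cr <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    if (sqrt(sum(cr^2)) < tol) {
      skipped <- c(skipped, ci)
      next
    }
    u <- .unit(-(a + b))
    v <- .unit(cr)
    out[[length(out) + 1]] <- list(
      carbon = ci,
      d1 = u * cos(half) + v * sin(half),
      d2 = u * cos(half) - v * sin(half)
    )
  }
  if (length(skipped)) {
    warning("skipped ", length(skipped),
            " collinear chain carbon(s): index ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  attr(out, "skipped") <- skipped
  out
}

.heavy_neighbours <- function(i, bonds, heavy) {
  nb <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
  nb[heavy[nb]]
}
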