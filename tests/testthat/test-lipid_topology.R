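# United-atom templates and geometric deuterium reconstruction.

# Molecular formulas of the underlying all-atom species, as an independent
# mass oracle (element masses from standard atomic weights).
formula_mass <- function(C = 0, H = 0, N = 0, O = 0, P = 0) {
  C * 12.011 + H * 1.008 + N * 14.007 + O * 15.999 + P * 30.974
}

test_that("POPC reduces to 52 particles implying 134 atoms", {
  t <- build_template("POPC")
  expect_identical(nrow(t$particles), 52L)
  expect_identical(sum(1L + t$particles$n_merged_h), 134L)
})

test_that("every template satisfies the structural invariants", {
  for (sp in template_species()) {
    t <- build_template(sp)
    p <- t$particles
    n <- nrow(p)
    expect_true(all(p$n_merged_h %in% 0:3), info = sp)
    expect_true(all(p$mass > 0), info = sp)
    expect_true(all(p$n_merged_h[p$element == "H"] == 0), info = sp)
    idx <- c(as.vector(t$bonds), t$sn1_chain, t$polar_marker_indices,
             if (!is.na(t$phosphate_index)) t$phosphate_index)
    expect_true(all(idx >= 1 & idx <= n), info = sp)
    # sn-1 chain indices pairwise bonded in order
    if (length(t$sn1_chain) > 1) {
      bk <- paste(pmin(t$bonds[, 1], t$bonds[, 2]),
                  pmax(t$bonds[, 1], t$bonds[, 2]))
      for (j in seq_len(length(t$sn1_chain) - 1)) {
        pr <- sort(t$sn1_chain[j + 0:1])
        expect_true(paste(pr[1], pr[2]) %in% bk, info = sp)
      }
    }
  }
})

test_that("template masses match the all-atom molecular formulas", {
  expected <- c(
    POPC = formula_mass(C = 42, H = 82, N = 1, O = 8, P = 1),
    CHOL = formula_mass(C = 27, H = 46, O = 1),
    OX1  = formula_mass(C = 42, H = 82, N = 1, O = 10, P = 1),
    OX2  = formula_mass(C = 33, H = 64, N = 1, O = 9, P = 1),
    OX3a = formula_mass(C = 33, H = 64, N = 1, O = 9, P = 1),
    OX3b = formula_mass(C = 9, H = 18, O = 1)
  )
  for (sp in names(expected)) {
    expect_equal(template_mass(build_template(sp)), expected[[sp]],
                 tolerance = 0.1 / expected[[sp]], info = sp)
  }
})

test_that("species-specific chemistry is encoded correctly", {
  chol <- build_template("CHOL")
  expect_identical(sum(chol$particles$element == "H"), 1L) # one hydroxyl H
  expect_length(chol$polar_marker_indices, 0)
  expect_length(build_template("POPC")$polar_marker_indices, 0)
  ox1 <- build_template("OX1")
  expect_identical(ox1$particles$element[ox1$polar_marker_indices], c("O", "O"))
  for (sp in c("OX2", "OX3a", "OX3b")) {
    t <- build_template(sp)
    expect_identical(t$particles$element[t$polar_marker_indices], "O", info = sp)
  }
  # OX3 pair: fragments carry separate templates; phosphate only on OX3a
  expect_false(is.na(build_template("OX3a")$phosphate_index))
  expect_true(is.na(build_template("OX3b")$phosphate_index))
  expect_error(build_template("DOPC"), "unknown lipid species")
})

test_that("deuteriums on an all-trans chain along z are perpendicular to it", {
  tpl <- build_template("POPC")
  coords <- lipid_conformation("POPC", tilt_deg = 0, template = tpl)
  dd <- reconstruct_deuteriums(coords, tpl)
  expect_length(dd, 14) # CD2 carbons C2..C15 only
  for (e in dd) {
    expect_lt(abs(e$d1[3]), 1e-6)
    expect_lt(abs(e$d2[3]), 1e-6)
  }
})

test_that("reconstructed deuteriums have exact geometry", {
  tpl <- build_template("POPC")
  geom <- deuterium_geometry()
  set.seed(4)
  coords <- lipid_conformation("POPC", tilt_deg = 25, azimuth = 1.1,
                               spin = 2.3, template = tpl)
  dd <- reconstruct_deuteriums(coords, tpl, geom)
  bonds <- tpl$bonds
  for (e in dd) {
    expect_equal(sqrt(sum(e$d1^2)), 1, tolerance = 1e-12)
    expect_equal(sqrt(sum(e$d2^2)), 1, tolerance = 1e-12)
    ang <- acos(sum(e$d1 * e$d2)) * 180 / pi
    expect_equal(ang, geom$hdh_angle, tolerance = 1e-6)
    # equal angles with both heavy neighbours (direct angle computation)
    nb <- c(bonds[bonds[, 1] == e$carbon, 2], bonds[bonds[, 2] == e$carbon, 1])
    nb <- nb[tpl$particles$element[nb] != "H"]
    a <- coords[nb[1], ] - coords[e$carbon, ]; a <- a / sqrt(sum(a^2))
    b <- coords[nb[2], ] - coords[e$carbon, ]; b <- b / sqrt(sum(b^2))
    expect_equal(sum(e$d1 * a), sum(e$d1 * b), tolerance = 1e-10)
    expect_equal(sum(e$d2 * a), sum(e$d2 * b), tolerance = 1e-10)
  }
})

test_that("deuterium reconstruction commutes with rigid rotation", {
  tpl <- build_template("POPC")
  coords <- lipid_conformation("POPC", tilt_deg = 10, spin = 0.4, template = tpl)
  # random rigid rotation from a QR decomposition
  set.seed(7)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  d0 <- reconstruct_deuteriums(coords, tpl)
  d1 <- reconstruct_deuteriums(coords %*% t(Q), tpl)
  for (k in seq_along(d0)) {
    expect_equal(as.vector(Q %*% d0[[k]]$d1), d1[[k]]$d1, tolerance = 1e-10)
    expect_equal(as.vector(Q %*% d0[[k]]$d2), d1[[k]]$d2, tolerance = 1e-10)
  }
})

test_that("collinear chain carbons are skipped with a warning", {
  tpl <- build_template("POPC")
  coords <- lipid_conformation("POPC", template = tpl)
  # straighten C4A-C5A-C6A into a line (chain positions 4,5,6)
  sn1 <- tpl$sn1_chain
  coords[sn1[5], ] <- (coords[sn1[4], ] + coords[sn1[6], ]) / 2
  expect_warning(dd <- reconstruct_deuteriums(coords, tpl), "collinear")
  expect_identical(attr(dd, "skipped"), sn1[5])
  expect_length(dd, 13)
})

test_that("templates serialize to a readable plain-text table", {
  path <- tempfile(fileext = ".tsv")
  write_template_table(build_template("POPC"), path)
  df <- read.delim(path, comment.char = "#")
  expect_identical(nrow(df), 52L)
  expect_identical(colnames(df), c("index", "name", "element", "n_merged_h", "mass"))
  expect_equal(sum(df$mass), template_mass(build_template("POPC")), tolerance = 1e-9)
})
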