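local_fixture <- function(kind, format = "pdb") {
  path <- withr::local_tempfile(fileext = paste0(".", format),
                                .local_envir = parent.frame())
  write_fixture_structure(kind, path, format = format)
  path
}

test_that("PDB and mmCIF readers agree on the same content", {
  p_pdb <- local_fixture("two_ion_kturn_like", "pdb")
  p_cif <- local_fixture("two_ion_kturn_like", "cif")
  a <- read_structure(p_pdb)
  b <- read_structure(p_cif)
  expect_identical(nrow(a), nrow(b))
  cols <- c("atom_name", "residue_name", "chain", "residue_number", "element")
  expect_identical(a[, cols], b[, cols])
  expect_lt(max(abs(a$x - b$x), abs(a$y - b$y), abs(a$z - b$z)), 1e-9)
})

test_that("written fixtures re-parse losslessly at coordinate precision", {
  p <- local_fixture("ideal_octahedron")
  a <- read_structure(p)
  expect_identical(nrow(a), 7L)
  expect_identical(sum(a$element == "MG"), 1L)
  # PDB coordinates carry 3 decimals
  expect_lt(max(abs(abs(a$x[a$element == "O"]) +
                      abs(a$y[a$element == "O"]) +
                      abs(a$z[a$element == "O"]) - 2.10)), 5e-4)
})

test_that("reader errors on truncated or alien files", {
  p <- withr::local_tempfile(lines = "ATOM      1  O6")
  expect_error(read_structure(p, format = "pdb"), class = "kt_format_error")
  p2 <- withr::local_tempfile(lines = c("just", "text"))
  expect_error(read_structure(p2, format = "pdb"), class = "kt_format_error")
  expect_error(read_structure(p2, format = "cif"), class = "kt_format_error")
  expect_error(read_structure("/nonexistent/file.pdb"), class = "kt_input_error")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  O6 AG   N   3       0.000   0.000   0.000  0.40  0.00           O",
    "ATOM      2  O6 BG   N   3       9.000   9.000   9.000  0.60  0.00           O",
    "END"), p)
  a <- read_structure(p)
  expect_identical(nrow(a), 1L)
  expect_equal(a$x, 9)
  expect_identical(a$altloc, "B")
})

test_that("the ideal octahedron scores deviation 0 and is octahedral", {
  sites <- find_metal_sites(read_structure(local_fixture("ideal_octahedron")))
  expect_length(sites, 1L)
  s <- sites[[1]]
  expect_identical(nrow(s$ligands), 6L)
  expect_lt(abs(s$cis_angle_deviation), 1e-9)
  expect_true(s$is_octahedral)
  expect_true(all(abs(s$ligands$distance - 2.10) < 5e-4))
})

test_that("cutoff preconditions and empty structures", {
  a <- read_structure(local_fixture("ideal_octahedron"))
  expect_error(find_metal_sites(a, cutoff = 1.0), class = "kt_precondition_error")
  expect_error(find_metal_sites(a, cutoff = 4.0), class = "kt_precondition_error")
  expect_identical(find_metal_sites(a[0, , drop = FALSE]), list())
  no_metal <- a[a$element != "MG", , drop = FALSE]
  expect_identical(find_metal_sites(no_metal), list())
})

test_that("a 4-ligand site is never octahedral; <2 ligands is a geometry error", {
  p <- withr::local_tempfile(fileext = ".pdb")
  # tetrahedral arrangement at 2.1 A
  t <- 2.1 / sqrt(3)
  verts <- rbind(c(t, t, t), c(t, -t, -t), c(-t, t, -t), c(-t, -t, t))
  lines <- c(sprintf("HETATM    1 MG   MG  A 101       0.000   0.000   0.000  1.00  0.00          MG"),
             vapply(1:4, function(i)
               sprintf("HETATM%5d  O   HOH W%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
                       i + 1, 200 + i, verts[i, 1], verts[i, 2], verts[i, 3]),
               character(1)),
             "END")
  writeLines(lines, p)
  s <- find_metal_sites(read_structure(p))[[1]]
  expect_identical(nrow(s$ligands), 4L)
  expect_false(s$is_octahedral)

  s$ligands <- s$ligands[1, , drop = FALSE]
  expect_error(octahedral_score(s), class = "kt_geometry_error")
})

test_that("a ligand displaced by 20 degrees shifts the mean cis deviation by 40/12", {
  # octahedron with the +y ligand rotated 20 deg toward +x: the two affected
  # cis angles become 70 and 110 deg, so the mean |cis - 90| is 40/12.
  p <- withr::local_tempfile(fileext = ".pdb")
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0),
                c(sin(20 * pi / 180), cos(20 * pi / 180), 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1)) * 2.1
  lines <- c("HETATM    1 MG   MG  A 101       0.000   0.000   0.000  1.00  0.00          MG",
             vapply(1:6, function(i)
               sprintf("HETATM%5d  O   HOH W%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
                       i + 1, 200 + i, dirs[i, 1], dirs[i, 2], dirs[i, 3]),
               character(1)),
             "END")
  writeLines(lines, p)
  s <- find_metal_sites(read_structure(p))[[1]]
  expect_equal(s$cis_angle_deviation, 40 / 12, tolerance = 1e-3)
  expect_true(s$is_octahedral)            # 3.33 deg within the 15 deg default
  sc5 <- octahedral_score(s, tolerance = 3)
  expect_false(sc5$is_octahedral)         # but not under a 3 deg tolerance
})

test_that("the two-ion fixture reproduces the reported O6 contact pattern", {
  sites <- find_metal_sites(read_structure(local_fixture("two_ion_kturn_like")))
  expect_length(sites, 2L)
  expect_true(all(vapply(sites, function(s) s$is_octahedral, logical(1))))
  rep <- guanine_O6_report(sites, two_ion_label_map())
  m1 <- rep[rep$metal_id == "M1", ]
  m2 <- rep[rep$metal_id == "M2", ]
  expect_setequal(m1$position_label, c("G2n", "G3n"))
  expect_identical(m2$position_label, "G3n")
  expect_true(all(rep$distance < 2.6))

  shared <- shared_ligand_report(sites)
  expect_identical(nrow(shared), 1L)
  expect_identical(shared$atom_name, "O6")
  expect_identical(shared$metals, "M1,M2")

  # without a mapping, rows carry residue numbers only
  bare <- guanine_O6_report(sites)
  expect_true(all(is.na(bare$position_label)))
  expect_identical(nrow(bare), 3L)
})

test_that("no metals means an empty O6 report", {
  a <- read_structure(local_fixture("two_ion_kturn_like"))
  sites <- find_metal_sites(a[a$element != "MG", , drop = FALSE])
  expect_identical(nrow(guanine_O6_report(sites)), 0L)
})

test_that("rigid-body transforms leave distances, angles and flags unchanged", {
  a <- read_structure(local_fixture("two_ion_kturn_like"))
  ref <- find_metal_sites(a)
  withr::with_seed(99, {
    for (rep_i in 1:5) {
      tf <- random_rigid_transform()
      got <- find_metal_sites(apply_rigid(a, tf))
      expect_length(got, length(ref))
      for (k in seq_along(ref)) {
        expect_equal(got[[k]]$ligands$distance, ref[[k]]$ligands$distance,
                     tolerance = 1e-9)
        expect_equal(got[[k]]$cis_angle_deviation,
                     ref[[k]]$cis_angle_deviation, tolerance = 1e-8)
        expect_identical(got[[k]]$is_octahedral, ref[[k]]$is_octahedral)
        expect_identical(got[[k]]$o6_contacts$residue_number,
                         ref[[k]]$o6_contacts$residue_number)
      }
    }
  })
})
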