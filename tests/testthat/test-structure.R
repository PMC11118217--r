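test_that("PDB parsing reads atoms, elements, and coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines(), f)
  model <- read_structure(f)
  expect_equal(nrow(model), 4L)
  expect_equal(model$element, c("N", "C", "S", "C"))
  expect_equal(model$residue_name[3], "CYS")
  expect_equal(model$x[2], 1.458)
  expect_equal(model$residue_number, c(1L, 1L, 1L, 2L))
})

test_that("multi-model NMR-style files load model 1 only", {
  f <- withr::local_tempfile(fileext = ".pdb")
  mk_atom <- function(serial, x) sprintf(
    "ATOM  %5d  CA  GLY A   1    %8.3f   0.000   0.000  1.00  0.00           C",
    serial, x)
  writeLines(c("MODEL        1", mk_atom(1, 0), "ENDMDL",
               "MODEL        2", mk_atom(1, 9), "ENDMDL",
               "MODEL        3", mk_atom(1, 18), "ENDMDL", "END"), f)
  model <- read_structure(f)
  expect_equal(nrow(model), 1L)
  expect_equal(model$x, 0)
})

test_that("mmCIF atom_site loops parse equivalently to PDB", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_toy",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N CYS A 1 0.000 0.000 0.000 1.00 1",
    "ATOM 2 C CA CYS A 1 1.458 0.000 0.000 1.00 1",
    "ATOM 3 S SG CYS A 1 2.000 1.500 0.500 1.00 1",
    "ATOM 4 C CA GLY A 2 4.100 0.200 -1.300 1.00 1",
    "ATOM 5 C CA GLY A 2 9.000 9.000 9.000 1.00 2",
    "#"), f)
  model <- read_structure(f, format = "mmcif")
  expect_equal(nrow(model), 4L)  # model 2 dropped
  expect_equal(model$element, c("N", "C", "S", "C"))
  expect_equal(model$y[3], 1.5)
})

test_that("generated structures round-trip through PDB write/read", {
  hp <- gen_structure(struct_spec("helix_peptide", sequence = "ACDMACDMC"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(hp$model, f)
  back <- read_structure(f)
  expect_equal(back$residue_name, hp$model$residue_name)
  expect_equal(back$residue_number, hp$model$residue_number)
  expect_lt(max(abs(as.matrix(back[, c("x", "y", "z")]) -
                    as.matrix(hp$model[, c("x", "y", "z")]))), 1e-3)
})

test_that("SASA matches the closed-form single-sphere and two-sphere solutions", {
  one <- gen_structure(struct_spec("single_atom"))
  s <- shrake_rupley(one$model, points = 960)
  analytic <- 4 * pi * (1.70 + 1.4)^2
  expect_equal(sum(s$per_atom$sasa), analytic, tolerance = 0.005)

  # far apart: no occlusion
  far <- gen_structure(struct_spec("sphere_pair", separation = 10))
  sf <- shrake_rupley(far$model, points = 960)
  expect_equal(sf$per_atom$sasa, rep(analytic, 2), tolerance = 0.005)

  # overlapping: spherical-cap solution within 1%
  near <- gen_structure(struct_spec("sphere_pair", separation = 3.5))
  sn <- shrake_rupley(near$model, points = 960)
  expect_equal(sn$per_atom$sasa, near$truth$analytic_sasa, tolerance = 0.01)

  expect_error(shrake_rupley(one$model, probe = -1), "positive")
  expect_error(shrake_rupley(one$model, points = 10), "92")
})

test_that("SASA converges with point count and matches a Monte-Carlo oracle", {
  set.seed(12)
  atoms <- tibble::tibble(
    serial = 1:30, element = sample(c("C", "N", "O", "S"), 30, TRUE),
    atom_name = "X", residue_name = "GLY", residue_number = 1:30,
    chain = "A", x = runif(30, 0, 10), y = runif(30, 0, 10),
    z = runif(30, 0, 10), occupancy = 1)
  model <- structure(atoms, class = c("crystal_structure", class(atoms)))
  s960 <- shrake_rupley(model, points = 960)$per_atom$sasa
  s4000 <- shrake_rupley(model, points = 4000)$per_atom$sasa
  expect_lt(abs(sum(s4000) - sum(s960)) / sum(s4000), 0.01)
  mc <- mc_sasa(model, npts = 4000, seed = 99)
  expect_lt(abs(sum(mc) - sum(s960)) / sum(mc), 0.02)
})

test_that("adding atoms can only reduce the SASA of the existing atoms", {
  inner <- gen_structure(struct_spec("shell_buried_cys", buried = TRUE,
                                     n_shell = 40, shell_radius = 6))$model
  s_before <- shrake_rupley(inner, points = 500)$per_atom$sasa
  # add a second, larger shell of atoms around everything
  extra <- tibble::tibble(
    serial = max(inner$serial) + 1:60, element = "C", atom_name = "CA",
    residue_name = "ALA", residue_number = max(inner$residue_number) + 1:60,
    chain = "A",
    x = 10 * cos(seq(0, 2 * pi, length.out = 60)),
    y = 10 * sin(seq(0, 2 * pi, length.out = 60)),
    z = rep(c(-2, 0, 2), 20), occupancy = 1)
  grown <- dplyr::bind_rows(tibble::as_tibble(inner), extra)
  grown <- structure(grown, class = c("crystal_structure", class(grown)))
  s_after <- shrake_rupley(grown, points = 500)$per_atom$sasa[seq_len(nrow(inner))]
  expect_true(all(s_after <= s_before + 1e-9))
})

test_that("domain cysteine sums respect the boundary and atom order", {
  hp <- gen_structure(struct_spec("helix_peptide", sequence = "CAAAAAAAC"))
  s <- shrake_rupley(hp$model)
  dom <- domain_cys_sasa(hp$model, s, boundary = 5)
  pr <- s$per_residue
  expect_equal(unname(dom["ntd"]), pr$sasa[pr$residue_number == 1])
  expect_equal(unname(dom["ctd"]), pr$sasa[pr$residue_number == 9])

  perm <- hp$model[rev(seq_len(nrow(hp$model))), ]
  perm <- structure(perm, class = class(hp$model))
  dom2 <- domain_cys_sasa(perm, shrake_rupley(perm), boundary = 5)
  expect_equal(dom2, dom, tolerance = 1e-9)

  nocys <- gen_structure(struct_spec("helix_peptide", sequence = "AAAA"))
  expect_warning(d0 <- domain_cys_sasa(nocys$model, boundary = 2), "no cysteine")
  expect_equal(unname(d0), c(0, 0))
  expect_error(domain_cys_sasa(hp$model, s, boundary = 99), "residue range")
})

test_that("buried-shell constructions give (near) zero cysteine SASA", {
  buried <- gen_structure(struct_spec("shell_buried_cys", buried = TRUE))
  s <- shrake_rupley(buried$model)
  dom <- domain_cys_sasa(buried$model, s, boundary = 1)
  expect_equal(unname(dom["ntd"]), 0, tolerance = 1e-6)
  exposed <- gen_structure(struct_spec("shell_buried_cys", buried = FALSE))
  se <- shrake_rupley(exposed$model)
  dome <- domain_cys_sasa(exposed$model, se, boundary = 1)
  expect_gt(unname(dome["ntd"]), 100)
})

test_that("the buried-control baseline follows direct arithmetic", {
  ctr <- tibble::tibble(id = c("p1", "p2"), control_sasa = c(2, 4))
  base <- buried_control_baseline(ctr)
  expect_equal(base$mean, 3)
  expect_equal(base$sd, sqrt(2), tolerance = 1e-9)
  expect_error(buried_control_baseline(tibble::tibble(id = "p1",
                                                      control_sasa = 2)),
               "sd undefined")
  eq <- tibble::tibble(id = c("a", "b", "c"), control_sasa = c(5, 5, 5))
  expect_equal(buried_control_baseline(eq)$sd, 0)
  expect_warning(
    base2 <- buried_control_baseline(tibble::tibble(
      id = c("a", "b", "c"), control_sasa = c(2, 4, NA))),
    "excluding")
  expect_equal(base2$n, 2L)
})

test_that("exposure classification applies the mean + SD threshold", {
  expect_equal(classify_exposure(0, 0, 3, 1), "neither")
  expect_equal(classify_exposure(50, 2, 3, 1), "NTD")
  expect_equal(classify_exposure(2, 50, 3, 1), "CTD")
  expect_equal(classify_exposure(50, 50, 3, 1), "both")
  expect_equal(classify_exposure(4.0, 0, 3, 1), "neither")  # not strictly above
  expect_error(classify_exposure(-1, 0, 3, 1), "non-negative")
})

test_that("exposure reports recover planted buried/exposed labels", {
  mk_two_domain <- function(ntd_exposed, ctd_exposed, ctrl_resno = 50) {
    shift <- function(m, dx, renum) {
      m$x <- m$x + dx
      m$residue_number <- m$residue_number + renum
      m
    }
    ntd <- gen_structure(struct_spec("shell_buried_cys", buried = !ntd_exposed,
                                     cys_resno = 1))$model
    ctd <- gen_structure(struct_spec("shell_buried_cys", buried = !ctd_exposed,
                                     cys_resno = 1))$model
    ctrl <- gen_structure(struct_spec("shell_buried_cys", buried = TRUE,
                                      cys_resno = 1))$model
    at <- dplyr::bind_rows(tibble::as_tibble(ntd),
                           shift(tibble::as_tibble(ctd), 60, 100),
                           shift(tibble::as_tibble(ctrl), 120, ctrl_resno - 1))
    at$serial <- seq_len(nrow(at))
    structure(at, class = c("crystal_structure", class(at)))
  }
  structures <- list(pN = mk_two_domain(TRUE, FALSE),
                     pC = mk_two_domain(FALSE, TRUE),
                     pB = mk_two_domain(TRUE, TRUE))
  rep <- exposure_report(structures,
                         boundaries = c(pN = 90, pC = 90, pB = 90),
                         controls = c(pN = 50, pC = 50, pB = 50),
                         points = 500)
  expect_equal(rep$exposure_class, c("NTD", "CTD", "both"))
  excl <- exclusivity_test(rep)
  expect_equal(excl$exceptions, "pB")
  expect_equal(sum(excl$counts$n), 3L)
})
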