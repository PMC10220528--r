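test_that("read_pdb parses a minimal water and respects CRYST1 presence", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   25.000   25.000   25.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  OW  HOH     1       1.000   2.000   3.000  1.00  0.00           O",
    "ATOM      2  H1  HOH     1       1.800   2.000   3.000  1.00  0.00           H",
    "ATOM      3  H2  HOH     1       0.700   2.900   3.000  1.00  0.00           H",
    "END"), p)
  r <- read_pdb(p)
  expect_equal(nrow(r$topology$atoms), 3)
  expect_equal(length(unique(r$topology$atoms$resid)), 1)
  expect_equal(r$frame$box, c(25, 25, 25))
  expect_equal(r$frame$coords[1, ], c(1, 2, 3))

  # no CRYST1 -> box unset, and PBC-dependent analyses must reject the frames
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(readLines(p)[-1], p2)
  r2 <- read_pdb(p2)
  expect_null(r2$frame$box)
  tr <- hs_trajectory(r2$topology, list(r2$frame))
  expect_error(rdf(tr, 1L, 2:3), "periodic box")
})

test_that("read_pdb rejects malformed records with the line number", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  OW  HOH     1       1.000   2.000   3.000  1.00  0.00           O",
    "ATOM      2  H1  HOH     1       1.800   xx.000   3.000  1.00  0.00          H"), p)
  expect_error(read_pdb(p), "line 2")
  p3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("ATOM      1  OW  HOH     1       1.000", p3)
  expect_error(read_pdb(p3), "line 1")
  # triclinic boxes are rejected, not silently accepted
  p4 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("CRYST1   25.000   25.000   25.000  90.00 120.00  90.00 P 1",
               "ATOM      1  OW  HOH     1       1.000   2.000   3.000"), p4)
  expect_error(read_pdb(p4), "orthorhombic")
})

test_that("PDB fixtures round-trip coordinates at format precision", {
  set.seed(42)
  tr <- gen_fjc(10, 1.5, n_samples = 2, seed = 7)
  dir <- withr::local_tempdir()
  paths <- write_fixture(tr, dir, "fjc")
  rt <- read_pdb(paths$pdb)
  expect_equal(rt$frame$coords, unname(tr$frames[[1]]$coords), tolerance = 1e-3)
  expect_equal(nrow(rt$topology$bonds), nrow(tr$topology$bonds))
})

test_that("multi-frame XYZ reads, round-trips and validates", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("4", "f0", "C 0 0 0", "C 1 0 0", "C 0 1 0", "C 0 0 1",
               "4", "f1", "C 0 0 0", "C 2 0 0", "C 0 2 0", "C 0 0 2"), p)
  fr <- read_xyz_multi(p, box = c(10, 10, 10))
  expect_length(fr, 2)
  expect_equal(nrow(fr[[1]]$coords), 4)
  expect_equal(fr[[2]]$coords[2, 1], 2)
  expect_equal(fr[[1]]$box, c(10, 10, 10))

  empty <- withr::local_tempfile(fileext = ".xyz")
  writeLines(character(0), empty)
  expect_error(read_xyz_multi(empty), "empty")

  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "f0", "C 0 0 0", "C 1 0 0", "3", "f1",
               "C 0 0 0", "C 1 0 0", "C 2 0 0"), bad)
  expect_error(read_xyz_multi(bad), "atom count")

  # write-then-read equals the written values at printed precision
  set.seed(3)
  co <- matrix(runif(30, -40, 40), 10, 3)
  out <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_multi(hs_frame(co), out)
  back <- read_xyz_multi(out)
  expect_identical(back[[1]]$coords, round(co, 6))
})

test_that("assign_roles classifies a PGE-like polymer and waters", {
  fx <- make_pge_topology(5)
  topo <- fx$topology
  expect_length(select_role(topo, "mainchain_oxygen"), 5)
  expect_length(select_role(topo, "sidechain_oxygen"), 5)
  expect_length(select_role(topo, "terminal_carbon"), 5)

  # water residue gets water roles only
  atoms <- rbind(topo$atoms,
                 data.frame(name = c("OW", "H1", "H2"), element = c("O", "H", "H"),
                            resid = 6, resname = "HOH"))
  t2 <- hs_topology(atoms, topo$bonds, 5)
  t2 <- assign_roles(t2, pge_role_map())
  widx <- which(atoms$resname == "HOH")
  expect_true(all(t2$roles[widx, c("water_oxygen", "water_hydrogen")] ==
                    cbind(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, TRUE))))
  expect_false(any(t2$roles[widx, c("backbone", "sidechain")]))

  # dropping the side-chain oxygen rule leaves polymer oxygens unclassified
  broken <- Filter(function(r) r$name != "O2", pge_role_map())
  expect_error(assign_roles(hs_topology(topo$atoms, topo$bonds, 5), broken),
               "not classified")
})

test_that("selections are ordered, set-algebraic and stable across re-read", {
  fx <- make_pge_topology(4)
  topo <- fx$topology
  expect_error(select_role(topo, "nonsense"), "unknown role")
  expect_identical(select_role(topo, "water_oxygen"), integer(0))
  term <- select_role(topo, "terminal_carbon")
  side <- select_role(topo, "sidechain")
  expect_identical(term, sort(term))
  expect_identical(intersect(term, side), term)        # terminal subset sidechain
  expect_identical(sort(union(select_role(topo, "mainchain_oxygen"),
                              select_role(topo, "sidechain_oxygen"))),
                   sort(which(topo$atoms$element == "O")))

  dir <- withr::local_tempdir()
  write_pdb(topo, fx$frame, file.path(dir, "pge.pdb"))
  re <- read_pdb(file.path(dir, "pge.pdb"))
  re$topology$n_residues_polymer <- 4L
  t3 <- assign_roles(re$topology, pge_role_map())
  expect_identical(select_role(t3, "terminal_carbon"), term)
})

test_that("topology invariants are enforced", {
  atoms <- data.frame(name = "C", element = "C", resid = 1, resname = "X")
  expect_error(hs_topology(atoms, matrix(c(1, 1), ncol = 2)), "self-bond")
  expect_error(hs_topology(atoms, matrix(c(1, 2), ncol = 2)), "nonexistent")
  expect_error(hs_topology(atoms, NULL, n_residues_polymer = 0), ">= 1")
  roles <- matrix(FALSE, 1, 7, dimnames = list(NULL, hydroshell:::.hs_roles))
  roles[1, c("backbone", "water_oxygen")] <- TRUE
  expect_error(hs_topology(atoms, NULL, 1, roles), "mutually exclusive")
  roles2 <- matrix(FALSE, 1, 7, dimnames = list(NULL, hydroshell:::.hs_roles))
  roles2[1, "terminal_carbon"] <- TRUE
  expect_error(hs_topology(atoms, NULL, 1, roles2), "sidechain")
  expect_error(hs_frame(matrix(1, 1, 3), box = c(-1, 2, 2)), "positive")
  expect_error(hs_trajectory(make_pge_topology(2)$topology, list()), ">= 1 frame")
})
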