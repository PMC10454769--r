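# Topology/trajectory loading, selections and pocket definition.

test_that("a multi-model PDB loads as one trajectory with its MODEL count", {
  pep <- ideal_peptide(6)
  m3 <- structure_model(pep$atoms, pep$xyz[rep(1, 3), ], condition = "x")
  path <- tempfile(fileext = ".pdb")
  write_models_pdb(m3, path)
  got <- load_structure(path)
  expect_equal(n_frames(got), 3L)
  expect_equal(nrow(got$traj_bounds), 1L)
  expect_equal(n_atoms(got), n_atoms(pep))
})

test_that("atom-count mismatch between topology and a frame file is a named error", {
  topo <- tempfile(fileext = ".pdb")
  frames <- tempfile(fileext = ".pdb")
  write_models_pdb(ideal_peptide(6), topo)
  write_models_pdb(ideal_peptide(5), frames)
  expect_error(load_structure(topo, frames),
               regexp = paste0("mismatch.*", basename(frames)))
})

test_that("write/read round trip preserves names, order and coordinates to PDB precision", {
  spec <- quick_spec(frames_per_trajectory = 4L)
  dir <- tempfile()
  write_synthetic(spec, dir, conditions = "A")
  model <- generate_condition(spec, "A")
  got <- load_structure(file.path(dir, "topology.pdb"),
                        file.path(dir, "cond_A_traj_1.pdb"))
  expect_identical(got$atoms$name, model$atoms$name)
  expect_identical(got$atoms$resid, model$atoms$resid)
  expect_lt(max(abs(got$xyz - model$xyz)), 1e-3 + 1e-9)
  # frame files listed in order define trajectory boundaries
  expect_equal(got$traj_bounds, data.frame(start = 1L, end = 4L))
})

test_that("BW ranges resolve to the contiguous construct range between anchors", {
  pep <- ideal_peptide(39)
  pep$atoms$resid <- pep$atoms$resid + 111L  # construct numbering 112..150
  model <- structure_model(pep$atoms, pep$xyz)
  bw <- bw_map(c(112L, 150L), c("3.41", "4.52"))
  idx <- resolve_selection(model, selection_spec(bw_range = "3.41-4.52",
                                                 atom_filter = "calpha"), bw)
  expect_length(idx, 39L)
  expect_true(all(model$atoms$name[idx] == "CA"))
  # missing anchor is an error naming the index
  expect_error(resolve_selection(model,
    selection_spec(bw_range = "3.41-9.99", atom_filter = "calpha"), bw),
    regexp = "9\\.99")
})

test_that("atom filters count atoms correctly and resolution is deterministic", {
  gly <- list(resid = 5L, chain = "A", resname = "GLY",
              atoms = list(N = c(0, 0, 0), CA = c(1.4, 0, 0),
                           C = c(2.1, 1.2, 0), O = c(3.3, 1.2, 0)))
  ala <- list(resid = 6L, chain = "A", resname = "ALA",
              atoms = list(N = c(0, 3, 0), CA = c(1.4, 3, 0),
                           C = c(2.1, 4.2, 0), O = c(3.3, 4.2, 0),
                           CB = c(1.4, 3, 1.5)))
  model <- toy_model(list(gly, ala))
  expect_length(resolve_selection(model, selection_spec(residues = 5L)), 4L)
  expect_length(resolve_selection(model, selection_spec(residues = 6L)), 5L)
  a <- resolve_selection(model, selection_spec(residues = 5:6))
  b <- resolve_selection(model, selection_spec(residues = c(6L, 5L)))
  expect_identical(a, b)  # order-independent, idempotent
  expect_error(resolve_selection(model, selection_spec(residues = 99L)),
               regexp = "99")
})

test_that("pocket selection honors the inclusive cutoff and unions conditions", {
  lig <- list(resid = 100L, chain = "L", resname = "LIG",
              atoms = list(C1 = c(0, 0, 0)))
  near <- list(resid = 1L, chain = "A", resname = "ALA",
               atoms = list(CA = c(4.4, 0, 0)))
  far <- list(resid = 2L, chain = "A", resname = "ALA",
              atoms = list(CA = c(0, 4.6, 0)))
  m1 <- toy_model(list(near, far, lig))
  sel <- pocket_selection(m1, selection_spec(chain = "L"), cutoff = 4.5)
  expect_identical(sel$residues, 1L)
  # at the boundary: exactly 4.5 is inside
  at45 <- toy_model(list(list(resid = 3L, chain = "A", resname = "ALA",
                              atoms = list(CA = c(4.5, 0, 0))), lig))
  expect_identical(pocket_selection(at45, selection_spec(chain = "L"))$residues, 3L)
  # union semantics across conditions
  m2 <- toy_model(list(list(resid = 2L, chain = "A", resname = "ALA",
                            atoms = list(CA = c(4.0, 0, 0))),
                       list(resid = 7L, chain = "A", resname = "ALA",
                            atoms = list(CA = c(0, 4.0, 0))), lig))
  u <- pocket_selection(list(m1, m2), selection_spec(chain = "L"))
  expect_identical(u$residues, c(1L, 2L, 7L))
  # zero cutoff yields an empty pocket; larger cutoffs only grow it
  expect_length(pocket_selection(m1, selection_spec(chain = "L"), 0)$residues, 0L)
  p3 <- pocket_selection(m1, selection_spec(chain = "L"), 3)$residues
  p6 <- pocket_selection(m1, selection_spec(chain = "L"), 6)$residues
  expect_true(all(p3 %in% p6))
})

test_that("pocket selection agrees with a brute-force distance scan on random toys", {
  set.seed(42)
  for (rep in 1:3) {
    co <- matrix(runif(3 * 12, 0, 12), ncol = 3)
    residues <- point_residues(co)
    residues[[13]] <- list(resid = 50L, chain = "L", resname = "LIG",
                           atoms = list(C1 = runif(3, 4, 8)))
    model <- toy_model(residues)
    sel <- pocket_selection(model, selection_spec(chain = "L"), 4.5)
    lig <- unlist(residues[[13]]$atoms)
    want <- which(sqrt(colSums((t(co) - lig)^2)) <= 4.5)
    expect_identical(sel$residues, as.integer(sort(want)))
  }
})

test_that("BW maps reject duplicates and report misses", {
  expect_error(bw_map(c(1L, 1L), c("1.50", "1.51")), regexp = "duplicate")
  expect_error(bw_map(1:2, c("1.50", "1.50")), regexp = "injective")
  map <- bw_map(1:3, c("1.49", "1.50", "IL2"))
  expect_warning(got <- bw_index(map, c(2L, 9L)), regexp = "9")
  expect_identical(got, c("1.50", NA))
  expect_identical(bw_resid(map, "IL2"), 3L)
  # text round trip
  path <- tempfile()
  writeLines(c("residue_id bw_index", "1 1.49", "2 1.50", "3 IL2"), path)
  expect_identical(read_bw_map(path)$bw, map$bw)
})
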