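# Kabsch superposition, evolution/pairwise RMSD and COM subsegment
# distances.

test_that("superposition recovers an exact rigid transform", {
  set.seed(37)
  ref <- matrix(rnorm(30), ncol = 3)
  theta <- pi / 2
  R <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0,
                0, 0, 1), 3, byrow = TRUE)
  mob <- sweep(ref %*% t(R), 2, c(3, -7, 2), "+")
  fit <- kabsch_superpose(mob, ref)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("reflection-related sets are fit with a proper rotation only", {
  set.seed(41)
  ref <- matrix(rnorm(24), ncol = 3)
  mob <- ref %*% diag(c(-1, 1, 1))  # mirror image
  fit <- kabsch_superpose(mob, ref)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_gt(fit$rmsd, 0.1)
})

test_that("rotations agree with the quaternion method on random sets", {
  set.seed(43)
  for (rep in 1:10) {
    ref <- matrix(rnorm(30), ncol = 3)
    mob <- matrix(rnorm(30), ncol = 3)
    fit <- kabsch_superpose(mob, ref)
    Rq <- quaternion_rotation(mob, ref)
    # same minimizer: rotations agree (both proper by construction)
    expect_lt(max(abs(fit$rotation %*% t(Rq) - diag(3))), 1e-8)
  }
})

test_that("collinear alignment sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), regexp = "collinear")
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               regexp = "3 alignment")
})

# a toy with a static 4-atom alignment frame (chain A) and a 1-atom ligand
# (chain L) whose x offset we control per frame
offset_model <- function(offsets) {
  base <- c(0, 0, 0, 4, 0, 0, 0, 4, 0, 0, 0, 4,  # 4 alignment atoms
            1, 1, 1)                               # ligand atom
  xyz <- t(vapply(offsets, function(d) {
    fr <- base
    fr[13] <- fr[13] + d
    fr
  }, numeric(15)))
  atoms <- data.frame(
    name = c("CA", "CA", "CA", "CA", "C1"),
    element = "C", mass = 12.011,
    resid = c(1L, 2L, 3L, 4L, 9L),
    resname = c(rep("ALA", 4), "LIG"),
    chain = c(rep("A", 4), "L"))
  structure_model(atoms, xyz, condition = "toy")
}

test_that("evolution RMSD is zero for static input and exact for a rigid offset", {
  align <- selection_spec(chain = "A")
  target <- selection_spec(chain = "L")
  m0 <- offset_model(c(0, 0, 0))
  expect_true(all(evolution_rmsd(m0, align, target)$rmsd == 0))
  m2 <- offset_model(c(0, 2, 0.5))
  r <- evolution_rmsd(m2, align, target)
  expect_equal(r$rmsd, c(0, 2, 0.5), tolerance = 1e-10)
})

test_that("evolution RMSD is invariant to rigid motion of whole frames", {
  m <- offset_model(c(0, 1.3, 0.4))
  r0 <- evolution_rmsd(m, selection_spec(chain = "A"), selection_spec(chain = "L"))
  theta <- 1.1
  R <- matrix(c(cos(theta), 0, sin(theta), 0, 1, 0,
                -sin(theta), 0, cos(theta)), 3, byrow = TRUE)
  m2 <- m
  for (f in 1:3) {
    co <- matrix(m$xyz[f, ], ncol = 3, byrow = TRUE) %*% t(R)
    m2$xyz[f, ] <- as.vector(t(sweep(co, 2, c(5, 6, 7) * f, "+")))
  }
  r2 <- evolution_rmsd(m2, selection_spec(chain = "A"), selection_spec(chain = "L"))
  expect_equal(r2$rmsd, r0$rmsd, tolerance = 1e-9)
})

test_that("evolution references the first frame of each trajectory independently", {
  m <- offset_model(c(0, 2, 5, 5, 5))
  m$traj_bounds <- data.frame(start = c(1L, 3L), end = c(2L, 5L))
  r <- evolution_rmsd(m, selection_spec(chain = "A"), selection_spec(chain = "L"))
  expect_equal(r$rmsd[r$trajectory == 1], c(0, 2))
  expect_equal(r$rmsd[r$trajectory == 2], c(0, 0, 0))  # traj 2 is static
})

test_that("pairwise RMSD reproduces hand-computable averages", {
  align <- selection_spec(chain = "A")
  target <- selection_spec(chain = "L")
  m0 <- offset_model(rep(0, 4))
  p0 <- pairwise_rmsd(m0, align, target, bootstrap_plan(2L, 4L, FALSE))
  expect_equal(p0$mean, 0)
  expect_equal(p0$sd, 0)
  # offsets 0,1,2: pair RMSDs {1,2,1}; exhaustive average 4/3
  m3 <- offset_model(c(0, 1, 2))
  p3 <- pairwise_rmsd(m3, align, target, bootstrap_plan(1L, 3L, FALSE))
  expect_equal(p3$mean, 4 / 3, tolerance = 1e-12)
  expect_error(pairwise_rmsd(m3, align, target, bootstrap_plan(1L, 1L, FALSE)),
               regexp = ">= 2")
})

test_that("pair order does not matter beyond numerical tolerance", {
  set.seed(47)
  spec <- quick_spec(frames_per_trajectory = 4L)
  m <- generate_condition(spec, "A")
  ai <- resolve_selection(m, selection_spec(chain = "R", atom_filter = "calpha"))
  ti <- resolve_selection(m, selection_spec(chain = "L"))
  co1 <- matrix(m$xyz[1, ], ncol = 3, byrow = TRUE)
  co2 <- matrix(m$xyz[2, ], ncol = 3, byrow = TRUE)
  ab <- allopath:::.fit_then_rmsd(co2, co1, ai, ti)
  ba <- allopath:::.fit_then_rmsd(co1, co2, ai, ti)
  expect_lt(abs(ab - ba), 1e-6)
})

test_that("COM distances reduce to point positions and match an independent oracle", {
  segs <- subsegment_set(list(s1 = 1L, s2 = 2L))
  m <- toy_model(list(
    list(resid = 1L, chain = "A", resname = "ALA", atoms = list(CA = c(0, 0, 0))),
    list(resid = 2L, chain = "A", resname = "ALA", atoms = list(CA = c(10, 0, 0)))))
  m10 <- structure_model(m$atoms, m$xyz[rep(1, 6), ])
  p <- pia_distances(m10, segs, bootstrap_plan(3L, 4L, seed = 5L))
  expect_equal(p$table$mean_dist, 10)
  expect_equal(p$table$sd, 0)

  set.seed(53)
  spec <- quick_spec(frames_per_trajectory = 6L)
  ms <- generate_condition(spec, "A")
  segs2 <- subsegment_set(list(a = 1:12, b = 13:24, c = 25:36))
  plan <- bootstrap_plan(1L, 6L, FALSE)
  got <- pia_distances(ms, segs2, plan)
  # independent mass-weighted COM computation
  oracle_com <- function(f, resids) {
    rows <- which(ms$atoms$resid %in% resids & toupper(ms$atoms$element) != "H")
    co <- matrix(ms$xyz[f, ], ncol = 3, byrow = TRUE)[rows, , drop = FALSE]
    w <- ms$atoms$mass[rows]
    colSums(co * w) / sum(w)
  }
  want_ab <- mean(vapply(1:6, function(f)
    sqrt(sum((oracle_com(f, 1:12) - oracle_com(f, 13:24))^2)), numeric(1)))
  expect_equal(got$table$mean_dist[got$table$seg_i == "a" &
                                     got$table$seg_j == "b"], want_ab,
               tolerance = 1e-10)
  # atom enumeration order cannot matter
  perm <- sample(nrow(ms$atoms))
  ms_perm <- structure_model(ms$atoms[perm, ],
                             ms$xyz[, as.vector(rbind(3 * perm - 2, 3 * perm - 1,
                                                      3 * perm)), drop = FALSE],
                             traj_bounds = ms$traj_bounds)
  got_perm <- pia_distances(ms_perm, segs2, plan)
  expect_equal(got_perm$table$mean_dist, got$table$mean_dist, tolerance = 1e-10)
})

test_that("subsegment sets validate names, emptiness and overlap; empty resolution errors", {
  expect_error(subsegment_set(list(21:27)), regexp = "named")
  expect_error(subsegment_set(list(a = integer())), regexp = "empty")
  expect_error(subsegment_set(list(a = 1:5, b = 5:9)), regexp = "overlap")
  d1r <- d1r_subsegments()
  expect_length(d1r$ranges, 21L)
  expect_identical(d1r$ranges[["5iL"]], 220:242)
  m <- toy_model(point_residues(matrix(rnorm(9), 3)))
  expect_error(pia_distances(m, subsegment_set(list(x = 99L)),
                             bootstrap_plan(1L, 1L, FALSE)), regexp = "zero atoms")
})

test_that("a planted rigid subsegment shift appears as a constant distance change", {
  co <- rbind(c(0, 0, 0), c(8, 0, 0), c(16, 0, 0), c(24, 0, 0))
  base <- toy_model(point_residues(co))
  m1 <- structure_model(base$atoms, base$xyz[rep(1, 5), ], condition = "1")
  shifted <- co; shifted[4, 1] <- shifted[4, 1] + 2
  b2 <- toy_model(point_residues(shifted))
  m2 <- structure_model(b2$atoms, b2$xyz[rep(1, 5), ], condition = "2")
  segs <- subsegment_set(list(a = 1L, b = 2L, c = 3L, d = 4L))
  plan <- bootstrap_plan(2L, 3L, seed = 8L)
  diff <- pia_difference(pia_distances(m1, segs, plan),
                         pia_distances(m2, segs, plan))
  d_involving <- diff$delta[diff$seg_i == "d" | diff$seg_j == "d"]
  expect_true(all(abs(d_involving - 2) < 1e-10))
  expect_true(all(diff$delta[diff$seg_i != "d" & diff$seg_j != "d"] == 0))
})
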