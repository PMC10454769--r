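# Synthetic two-condition trajectory ensembles of a seven-helix bundle with
# a bound small molecule and a second ("G-alpha") chain.
#
# The generator is a statistical mimic, not a force field: helical segments
# follow ideal alpha-helix backbone geometry so the secondary-structure
# stage assigns them helix; a designated window of residues switches
# cooperatively between helix and coil under a two-state Markov chain with
# condition-dependent rates (coil frames displace the window backbone
# radially outward, breaking its i->i+4 hydrogen bonds); residue-residue
# contacts are planted per frame as Bernoulli events by moving one
# sidechain pseudo-atom (CB) toward its partner; the ligand jitters
# isotropically about a fixed pose.  Every planted effect is therefore a
# known ground truth that the analysis stages must recover.

# ---- ideal-geometry construction (NeRF internal-coordinate chain) --------

# place atom D given A-B-C, bond |CD|, angle B-C-D and dihedral A-B-C-D
# (degrees)
.place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- .unit(c - b)
  nrm <- .unit(.cross3(b - a, bc))
  m <- .cross3(nrm, bc)
  d_local <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + cbind(bc, m, nrm) %*% d_local
}

# backbone (+CB) of an n-residue chain with fixed phi/psi/omega; standard
# bond lengths and angles; returns list of n x 3 matrices
.ideal_chain <- function(n, phi = -57, psi = -47, omega = 180, cb = TRUE) {
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- CA[1, ] + 1.525 * c(cos(pi - 111.2 * pi / 180), sin(pi - 111.2 * pi / 180), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.2, psi)
      CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.7, omega)
      C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi)
    }
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.5, psi + 180)
    if (cb) CB[i, ] <- .place_atom(C[i, ], N[i, ], CA[i, ], 1.521, 110.4, 122.55)
  }
  list(N = N, CA = CA, C = C, O = O, CB = if (cb) CB else NULL)
}

# rigid-transform a chain so the CA principal axis runs along +z, the CA
# centroid sits on the z axis, and the first CA is at the lowest z
.axis_align <- function(chain) {
  CA <- chain$CA
  ctr <- colMeans(CA)
  X <- sweep(CA, 2, ctr)
  ax <- svd(X, nu = 0, nv = 3)$v[, 1]
  if (sum(ax * (CA[nrow(CA), ] - CA[1, ])) < 0) ax <- -ax
  z <- c(0, 0, 1)
  v <- .cross3(ax, z)
  s <- .vnorm(v)
  if (s < 1e-12) {
    Rot <- diag(3)
  } else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, byrow = TRUE)
    Rot <- diag(3) + vx + vx %*% vx * ((1 - sum(ax * z)) / s^2)
  }
  tr <- function(M) {
    if (is.null(M)) return(NULL)
    sweep(M, 2, ctr) %*% t(Rot)
  }
  out <- lapply(chain, tr)
  zmin <- min(out$CA[, 3])
  lapply(out, function(M) if (is.null(M)) NULL else sweep(M, 2, c(0, 0, zmin), "-"))
}

.rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1),
         3, byrow = TRUE)
}

#' Ideal poly-alanine peptide as a one-frame structure model
#'
#' Builds an n-residue chain with the given backbone dihedrals (defaults:
#' ideal alpha helix) and standard bond geometry; useful as a geometric
#' reference for the secondary-structure stage.
#'
#' @param n number of residues.
#' @param phi,psi backbone dihedrals in degrees (`phi = psi = 180` gives a
#'   fully extended strand).
#' @param chain chain id.
#' @return A [structure_model()] with one frame.
#' @export
ideal_peptide <- function(n, phi = -57, psi = -47, chain = "A") {
  ch <- .ideal_chain(n, phi, psi)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(name = c("N", "CA", "C", "O", "CB"),
               element = c("N", "C", "C", "O", "C"),
               mass = .mass_of(c("N", "C", "C", "O", "C")),
               resid = i, resname = "ALA", chain = chain)))
  co <- do.call(rbind, lapply(seq_len(n), function(i)
    rbind(ch$N[i, ], ch$CA[i, ], ch$C[i, ], ch$O[i, ], ch$CB[i, ])))
  structure_model(atoms, matrix(as.vector(t(co)), nrow = 1),
                  condition = sprintf("ideal(phi=%g,psi=%g)", phi, psi))
}

# ---- specification -------------------------------------------------------

#' Specification of a synthetic two-condition ensemble
#'
#' Defines a seven-helix receptor bundle (chain `R`), a G-alpha helix
#' (chain `G`) and a bound ligand (chain `L`), together with the planted
#' condition differences: a cooperative helix/coil window with per-frame
#' Markov switch rates, residue-pair contacts realized as per-frame
#' Bernoulli events at condition-dependent target frequencies (including a
#' "hub" whose edges strengthen, mimicking an allosteric tightening), and
#' receptor/G-alpha interface contacts.  Residue pairs for the planted
#' contacts are chosen deterministically from the bundle geometry (the
#' facing pair of sidechain pseudo-atoms of the requested helix pair).
#'
#' @param n_helices receptor helix count.
#' @param residues_per_helix residues per receptor helix.
#' @param n_trajectories independent trajectories per condition.
#' @param frames_per_trajectory frames per trajectory.
#' @param bundle_radius radius of the helix-axis circle (Angstrom).
#' @param window_rates per-condition Markov rates for the helix window:
#'   list of named vectors `c(on, off)` with `on` the coil-to-helix and
#'   `off` the helix-to-coil per-frame probability.  The defaults give
#'   stationary helix occupancies of 0.25 (condition A) and 0.85 (B).
#' @param planted_contacts helix-level plant table (columns `tag`,
#'   `helix_i`, `helix_j`, `freq_a`, `freq_b`); rows tagged `"hub"` share
#'   the helix_i-side residue.  `NULL` uses the default hub + loss +
#'   background table.
#' @param interface_contacts receptor/G-alpha plant table (columns `tag`,
#'   `helix`, `freq_a`, `freq_b`); `NULL` uses two strengthening pairs
#'   (0.30 to 0.45) and one static pair.
#' @param galpha_residues,galpha_gap G-alpha helix length and axis gap from
#'   the bundle circle (Angstrom).
#' @param ligand_atoms,ligand_sigma,ligand_offset ligand heavy-atom count,
#'   per-frame isotropic positional jitter (Angstrom) and radial offset of
#'   the pose from the bundle circle.
#' @param thermal_sigma per-frame isotropic jitter of all protein atoms.
#' @param window_displacement radial outward displacement (Angstrom) of
#'   the window backbone in coil frames; large enough to break all i->i+4
#'   hydrogen bonds through the window.
#' @param segment_shift optional rigid displacement planted on a residue
#'   set in one condition: `list(residues =, shift = c(x, y, z),
#'   condition = "B")`.
#' @param seed integer master seed; trajectories derive deterministic
#'   sub-seeds, so regeneration is byte-identical.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_helices = 7L, residues_per_helix = 12L,
                           n_trajectories = 3L, frames_per_trajectory = 1000L,
                           bundle_radius = 15,
                           window_rates = list(A = c(on = 0.10, off = 0.30),
                                               B = c(on = 0.34, off = 0.06)),
                           planted_contacts = NULL,
                           interface_contacts = NULL,
                           galpha_residues = 16L, galpha_gap = 13,
                           ligand_atoms = 8L, ligand_sigma = 0.5,
                           ligand_offset = 7,
                           thermal_sigma = 0.10,
                           window_displacement = 8,
                           segment_shift = NULL,
                           seed = 1L) {
  if (is.null(planted_contacts)) {
    nh <- n_helices
    adj <- cbind(seq_len(nh), c(seq_len(nh)[-1], 1L))
    planted_contacts <- rbind(
      data.frame(tag = c("hub", "gain", "loss"),
                 helix_i = c(1L, 5L, 4L), helix_j = c(2L, 6L, 5L),
                 freq_a = c(0.30, 0.30, 0.60),
                 freq_b = c(0.80, 0.80, 0.35)),
      data.frame(tag = paste0("bg", seq_len(nh)),
                 helix_i = adj[, 1], helix_j = adj[, 2],
                 freq_a = 0.70, freq_b = 0.70))
  }
  if (is.null(interface_contacts)) {
    interface_contacts <- data.frame(
      tag = c("if1", "if2", "if0"), helix = 5L,
      freq_a = c(0.30, 0.30, 0.60), freq_b = c(0.45, 0.45, 0.60))
  }
  for (tab in list(planted_contacts, interface_contacts)) {
    f <- unlist(tab[grepl("^freq", names(tab))])
    if (any(f < 0 | f > 1)) .stopf("planted contact frequencies must lie in [0, 1]")
  }
  for (r in window_rates)
    if (any(r < 0 | r > 1)) .stopf("window switch probabilities must lie in [0, 1]")
  if (ligand_sigma < 0 || thermal_sigma < 0) .stopf("jitter sigma must be >= 0")
  structure(list(
    n_helices = as.integer(n_helices),
    residues_per_helix = as.integer(residues_per_helix),
    n_trajectories = as.integer(n_trajectories),
    frames_per_trajectory = as.integer(frames_per_trajectory),
    bundle_radius = bundle_radius, window_rates = window_rates,
    planted_contacts = planted_contacts,
    interface_contacts = interface_contacts,
    galpha_residues = as.integer(galpha_residues), galpha_gap = galpha_gap,
    ligand_atoms = as.integer(ligand_atoms), ligand_sigma = ligand_sigma,
    ligand_offset = ligand_offset, thermal_sigma = thermal_sigma,
    window_displacement = window_displacement,
    segment_shift = segment_shift, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic_spec: %d helices x %d residues + G-alpha(%d) + ligand(%d)\n",
              x$n_helices, x$residues_per_helix, x$galpha_residues, x$ligand_atoms))
  cat(sprintf("%d trajectories x %d frames per condition; seed %d\n",
              x$n_trajectories, x$frames_per_trajectory, x$seed))
  cat(sprintf("planted contacts: %d; interface: %d\n",
              nrow(x$planted_contacts), nrow(x$interface_contacts)))
  invisible(x)
}

# ---- topology + plant resolution ----------------------------------------

# residue id range of receptor helix h
.helix_resids <- function(spec, h) {
  m <- spec$residues_per_helix
  ((h - 1L) * m + 1L):(h * m)
}

# window residues: three central residues of helix 3 by default
.window_resids <- function(spec) {
  r <- .helix_resids(spec, min(3L, spec$n_helices))
  mid <- r[ceiling(length(r) / 2)]
  (mid - 1L):(mid + 1L)
}

#' Resolve a synthetic specification to its concrete topology and plants
#'
#' Deterministically derives the atom table, canonical coordinates,
#' residue-level plant assignments (which residue pairs realize each
#' planted contact, and the contact-pose of each mover sidechain atom) and
#' the helix-window membership.  Exposed so tests and pipelines can obtain
#' the planted ground truth without generating frames.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `atoms`, `x0` (canonical coordinates, atoms x 3),
#'   `plants` (resolved residue-level table), `window` (residue ids),
#'   `galpha_resids`, `ligand_resid`.
#' @export
resolve_synthetic <- function(spec) {
  nh <- spec$n_helices
  m <- spec$residues_per_helix
  stopifnot(nh >= 2L, m >= 7L)
  template <- .axis_align(.ideal_chain(m))
  gtempl <- .axis_align(.ideal_chain(spec$galpha_residues))
  R <- spec$bundle_radius
  ang <- 2 * pi * (seq_len(nh) - 1) / nh

  place_chain <- function(tmpl, theta, radius, zoff = 0) {
    Rot <- .rot_z(theta)
    shift <- c(radius * cos(theta), radius * sin(theta), zoff)
    lapply(tmpl, function(M) if (is.null(M)) NULL else
      sweep(M %*% t(Rot), 2, shift, "+"))
  }

  atoms <- list(); coords <- list()
  add_residue <- function(resid, resname, chain, names, elements, co) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      name = names, element = elements, mass = .mass_of(elements),
      resid = resid, resname = resname, chain = chain)
    coords[[length(coords) + 1]] <<- co
  }

  bbn <- c("N", "CA", "C", "O", "CB")
  bbe <- c("N", "C", "C", "O", "C")
  for (h in seq_len(nh)) {
    ch <- place_chain(template, ang[h], R)
    for (i in seq_len(m)) {
      add_residue((h - 1L) * m + i, "ALA", "R", bbn, bbe,
                  rbind(ch$N[i, ], ch$CA[i, ], ch$C[i, ], ch$O[i, ], ch$CB[i, ]))
    }
  }
  ga_first <- nh * m + 101L
  galpha_resids <- ga_first:(ga_first + spec$galpha_residues - 1L)
  gch <- place_chain(gtempl, ang[min(5L, nh)], R + spec$galpha_gap)
  for (i in seq_len(spec$galpha_residues)) {
    add_residue(galpha_resids[i], "ALA", "G", bbn, bbe,
                rbind(gch$N[i, ], gch$CA[i, ], gch$C[i, ], gch$O[i, ], gch$CB[i, ]))
  }
  lig_resid <- ga_first + 200L
  nl <- spec$ligand_atoms
  lig_local <- cbind(1.6 * cos(2 * pi * seq_len(nl) / nl),
                     1.6 * sin(2 * pi * seq_len(nl) / nl),
                     0.45 * (seq_len(nl) - (nl + 1) / 2))
  lig_ctr <- c((R + spec$ligand_offset) * cos(ang[1]),
               (R + spec$ligand_offset) * sin(ang[1]),
               mean(template$CA[, 3]))
  add_residue(lig_resid, "LIG", "L", paste0("C", seq_len(nl)),
              rep("C", nl), sweep(lig_local, 2, lig_ctr, "+"))

  atoms <- do.call(rbind, atoms)
  x0 <- do.call(rbind, coords)

  cb_row <- setNames(which(atoms$name == "CB"),
                     atoms$resid[atoms$name == "CB"])
  window <- .window_resids(spec)

  # ---- deterministic, pose-aware residue picking for planted contacts ----
  # Candidate pairs are tried in order of increasing sidechain (CB-CB)
  # distance; a pair is accepted only if its contact pose reaches nothing
  # but the partner: clear of every other residue (canonical and
  # window-displaced positions), of the ligand, and of every previously
  # accepted pose, all by the same margin that keeps baseline noise from
  # flipping contacts.
  margin <- 5.0        # baseline separation: noise cannot create contacts
  margin_pose <- 4.8   # pose clearance: rare noise flips stay far below
                       # the 0.10 difference-display threshold
  excluded <- c(window - 1L, window, window + 1L)
  interior <- function(resids) setdiff(resids[2:(length(resids) - 1L)], excluded)
  used <- integer(0)
  poses <- matrix(numeric(0), 0, 3)
  cb_of <- function(r) x0[cb_row[as.character(r)], ]
  prot_rows <- which(atoms$chain %in% c("R", "G"))
  lig_rows <- which(atoms$chain == "L")
  wrows_all <- which(atoms$resid %in% window)
  wdir <- c(cos(ang[min(3L, nh)]), sin(ang[min(3L, nh)]), 0)
  wdisp_coords <- x0[wrows_all, , drop = FALSE] +
    matrix(spec$window_displacement * wdir, length(wrows_all), 3, byrow = TRUE)

  pose_ok <- function(ri, rj) {
    rows_pair <- which(atoms$resid %in% c(ri, rj))
    base <- min(.cdist(x0[which(atoms$resid == ri), , drop = FALSE],
                       x0[which(atoms$resid == rj), , drop = FALSE]))
    if (base <= margin) return(NULL)
    pose <- cb_of(ri) + 4.0 * .unit(cb_of(rj) - cb_of(ri))
    others <- setdiff(prot_rows, rows_pair)
    if (min(sqrt(rowSums(sweep(x0[others, , drop = FALSE], 2, pose)^2))) <= margin_pose)
      return(NULL)
    if (length(lig_rows) &&
        min(sqrt(rowSums(sweep(x0[lig_rows, , drop = FALSE], 2, pose)^2))) <= margin_pose)
      return(NULL)
    if (min(sqrt(rowSums(sweep(wdisp_coords, 2, pose)^2))) <= margin_pose)
      return(NULL)
    if (nrow(poses) &&
        min(sqrt(rowSums(sweep(poses, 2, pose)^2))) <= margin)
      return(NULL)
    pose
  }
  pick <- function(candA, candB, anchor = NULL, tag = "") {
    candA <- setdiff(candA, used)
    candB <- setdiff(candB, used)
    if (!is.null(anchor)) candA <- anchor
    if (!length(candA) || !length(candB))
      .stopf("planted contact '%s' unrealizable: no free residues left", tag)
    dm <- outer(candA, candB,
                Vectorize(function(a, b) .vnorm(cb_of(a) - cb_of(b))))
    ord <- order(dm)
    for (k in ord) {
      idx <- arrayInd(k, dim(dm))
      ri <- candA[idx[1]]; rj <- candB[idx[2]]
      pose <- pose_ok(ri, rj)
      if (!is.null(pose)) return(list(ri = ri, rj = rj, pose = pose))
    }
    .stopf("planted contact '%s' unrealizable: every candidate pair clashes", tag)
  }

  plants <- list()
  hub_res <- NA_integer_
  pc <- spec$planted_contacts
  for (r in seq_len(nrow(pc))) {
    hi <- .helix_resids(spec, pc$helix_i[r])
    hj <- .helix_resids(spec, pc$helix_j[r])
    anchor <- if (identical(pc$tag[r], "hub") && !is.na(hub_res)) hub_res
    sel <- pick(interior(hi), interior(hj), anchor, pc$tag[r])
    if (identical(pc$tag[r], "hub") && is.na(hub_res)) hub_res <- sel$ri
    used <- c(used, sel$ri, sel$rj)
    poses <- rbind(poses, sel$pose)
    plants[[length(plants) + 1]] <- data.frame(
      tag = pc$tag[r], res_i = sel$ri, res_j = sel$rj, mover = sel$rj,
      chain_i = "R", chain_j = "R",
      freq_a = pc$freq_a[r], freq_b = pc$freq_b[r],
      pose_x = sel$pose[1], pose_y = sel$pose[2], pose_z = sel$pose[3])
  }
  ic <- spec$interface_contacts
  g_interior <- galpha_resids[2:(length(galpha_resids) - 1L)]
  for (r in seq_len(nrow(ic))) {
    hi <- .helix_resids(spec, ic$helix[r])
    sel <- pick(interior(hi), g_interior, tag = ic$tag[r])
    used <- c(used, sel$ri, sel$rj)
    poses <- rbind(poses, sel$pose)
    plants[[length(plants) + 1]] <- data.frame(
      tag = ic$tag[r], res_i = sel$ri, res_j = sel$rj, mover = sel$rj,
      chain_i = "R", chain_j = "G",
      freq_a = ic$freq_a[r], freq_b = ic$freq_b[r],
      pose_x = sel$pose[1], pose_y = sel$pose[2], pose_z = sel$pose[3])
  }
  plants <- do.call(rbind, plants)

  out <- list(atoms = atoms, x0 = x0, plants = plants, window = window,
              galpha_resids = galpha_resids, ligand_resid = lig_resid,
              cb_row = cb_row,
              window_dir = c(cos(ang[min(3L, nh)]), sin(ang[min(3L, nh)]), 0))
  .validate_synthetic(spec, out)
  out
}

# geometric feasibility: the canonical bundle must be contact-free between
# chains/helices, each contact pose must reach only its own partner, and
# the displaced window must not collide with anything
.validate_synthetic <- function(spec, topo) {
  at <- topo$atoms
  x0 <- topo$x0
  margin <- 5.0       # cutoff 4.5 + noise allowance (baseline geometry)
  margin_pose <- 4.8  # clearance required of contact poses
  prot <- at$chain %in% c("R", "G")
  helix_of <- ifelse(at$chain == "R",
                     (at$resid - 1L) %/% spec$residues_per_helix + 1L, NA)

  res_of_rows <- split(seq_len(nrow(at))[prot], at$resid[prot])
  ids <- as.integer(names(res_of_rows))
  first <- vapply(res_of_rows, `[`, 0L, 1)
  res_chain <- at$chain[first]
  res_helix <- helix_of[first]

  ctr <- t(vapply(res_of_rows, function(rw) colMeans(x0[rw, , drop = FALSE]), numeric(3)))
  n <- length(ids)
  # candidate clashes: residue centers closer than margin + 2*max radius
  rad <- vapply(seq_len(n), function(i)
    max(sqrt(rowSums((x0[res_of_rows[[i]], , drop = FALSE] -
                        matrix(ctr[i, ], length(res_of_rows[[i]]), 3, byrow = TRUE))^2))),
    numeric(1))
  min_pair_dist <- function(i, j) {
    min(.cdist(x0[res_of_rows[[i]], , drop = FALSE],
               x0[res_of_rows[[j]], , drop = FALSE]))
  }
  planted_key <- paste(pmin(topo$plants$res_i, topo$plants$res_j),
                       pmax(topo$plants$res_i, topo$plants$res_j))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_helix <- !is.na(res_helix[i]) && !is.na(res_helix[j]) &&
      res_helix[i] == res_helix[j]
    if (same_helix) next  # intra-helix packing is condition-invariant
    if (res_chain[i] == res_chain[j] && abs(ids[i] - ids[j]) <= 6L) next
    if (.vnorm(ctr[i, ] - ctr[j, ]) > margin + rad[i] + rad[j]) next
    if (paste(pmin(ids[i], ids[j]), pmax(ids[i], ids[j])) %in% planted_key) next
    if (min_pair_dist(i, j) <= margin)
      .stopf("synthetic geometry: residues %d and %d are within %.1f A at baseline",
             ids[i], ids[j], margin)
  }

  # contact poses: reach the partner, clash with nothing else
  for (k in seq_len(nrow(topo$plants))) {
    p <- topo$plants[k, ]
    pose <- c(p$pose_x, p$pose_y, p$pose_z)
    others <- prot & !(at$resid %in% c(p$res_i, p$res_j))
    dmin <- min(sqrt(rowSums(sweep(x0[others, , drop = FALSE], 2, pose)^2)))
    if (dmin <= margin_pose)
      .stopf("planted contact %d-%d unrealizable: pose clashes with another residue (%.2f A)",
             p$res_i, p$res_j, dmin)
    lig <- at$chain == "L"
    if (min(sqrt(rowSums(sweep(x0[lig, , drop = FALSE], 2, pose)^2))) <= margin_pose)
      .stopf("planted contact %d-%d unrealizable: pose clashes with the ligand",
             p$res_i, p$res_j)
    base <- min_pair_dist(match(p$res_i, ids), match(p$res_j, ids))
    if (base <= margin)
      .stopf("planted contact %d-%d unrealizable: baseline distance %.2f A already in contact range",
             p$res_i, p$res_j, base)
  }

  # displaced window clears everything outside the window's own helix
  wrows <- which(at$resid %in% topo$window)
  disp <- x0[wrows, , drop = FALSE] +
    matrix(spec$window_displacement * topo$window_dir, length(wrows), 3, byrow = TRUE)
  whelix <- unique(helix_of[wrows])
  rest <- which(prot & !(helix_of %in% whelix) | at$chain == "G")
  if (min(.cdist(disp, x0[rest, , drop = FALSE])) <= margin)
    .stopf("displaced helix window collides with the rest of the bundle")
  invisible(TRUE)
}

# two-state Markov chain sample: 1 = helix, 0 = coil; starts from the
# stationary distribution; uses exactly F uniform draws
.markov_states <- function(n, on, off) {
  pi_h <- if (on + off > 0) on / (on + off) else 1
  u <- runif(n)
  s <- integer(n)
  s[1] <- as.integer(u[1] < pi_h)
  for (t in seq_len(n - 1L)) {
    s[t + 1L] <- if (s[t] == 1L) as.integer(u[t + 1L] >= off)
    else as.integer(u[t + 1L] < on)
  }
  s
}

#' Generate one condition of a synthetic ensemble
#'
#' Deterministic given `spec$seed` and the condition label: each
#' trajectory derives its own sub-seed, so regeneration is byte-identical
#' and conditions A and B share the topology exactly.
#'
#' @param spec a [synthetic_spec()].
#' @param condition `"A"` or `"B"`.
#' @return A [structure_model()]; the resolved planted ground truth is
#'   attached as attribute `"truth"` (list with `plants`, `window`,
#'   `window_rates`, `galpha_resids`, `ligand_resid`).
#' @export
generate_condition <- function(spec, condition = c("A", "B")) {
  condition <- match.arg(condition)
  topo <- resolve_synthetic(spec)
  at <- topo$atoms
  A <- nrow(at)
  x0 <- topo$x0
  if (!is.null(spec$segment_shift) &&
      identical(spec$segment_shift$condition, condition)) {
    sh <- spec$segment_shift
    overlap <- intersect(sh$residues, c(topo$plants$res_i, topo$plants$res_j, topo$window))
    if (length(overlap))
      .stopf("segment_shift overlaps planted residues: %s",
             paste(overlap, collapse = ", "))
    rows <- which(at$resid %in% sh$residues)
    x0[rows, ] <- sweep(x0[rows, , drop = FALSE], 2, sh$shift, "+")
  }
  x0vec <- as.vector(t(x0))

  sig <- rep(spec$thermal_sigma, A)
  sig[at$chain == "L"] <- spec$ligand_sigma
  sig3 <- rep(sig, each = 3)

  freq_col <- if (condition == "A") "freq_a" else "freq_b"
  rates <- spec$window_rates[[condition]]
  wrows <- which(at$resid %in% topo$window)
  wdisp <- spec$window_displacement * topo$window_dir
  wcols <- as.vector(rbind(3 * wrows - 2, 3 * wrows - 1, 3 * wrows))

  Ftr <- spec$frames_per_trajectory
  xyz_list <- vector("list", spec$n_trajectories)
  for (tr in seq_len(spec$n_trajectories)) {
    xyz_list[[tr]] <- .with_seed(
      .sub_seed(spec$seed, paste0("cond:", condition, ":traj:", tr)), {
        xyz <- matrix(x0vec, Ftr, 3L * A, byrow = TRUE) +
          matrix(rnorm(Ftr * 3L * A), Ftr) * matrix(sig3, Ftr, 3L * A, byrow = TRUE)
        st <- .markov_states(Ftr, rates[["on"]], rates[["off"]])
        coil <- which(st == 0L)
        if (length(coil)) {
          add <- matrix(rep(wdisp, length(wrows)), length(coil),
                        3L * length(wrows), byrow = TRUE)
          xyz[coil, wcols] <- xyz[coil, wcols] + add
        }
        for (k in seq_len(nrow(topo$plants))) {
          p <- topo$plants[k, ]
          hit <- which(runif(Ftr) < p[[freq_col]])
          if (!length(hit)) next
          mrow <- topo$cb_row[as.character(p$mover)]
          mcols <- (3 * mrow - 2):(3 * mrow)
          shift <- c(p$pose_x, p$pose_y, p$pose_z) - x0[mrow, ]
          xyz[hit, mcols] <- xyz[hit, mcols] +
            matrix(shift, length(hit), 3, byrow = TRUE)
        }
        xyz
      })
  }
  xyz <- do.call(rbind, xyz_list)
  ends <- cumsum(rep(Ftr, spec$n_trajectories))
  model <- structure_model(at, xyz,
                           traj_bounds = data.frame(start = c(1L, utils::head(ends, -1) + 1L),
                                                    end = ends),
                           condition = condition)
  attr(model, "truth") <- list(plants = topo$plants, window = topo$window,
                               window_rates = spec$window_rates,
                               galpha_resids = topo$galpha_resids,
                               ligand_resid = topo$ligand_resid)
  model
}

#' Ballesteros-Weinstein map for a synthetic bundle
#'
#' Receptor residues are numbered `h.(44 + position)` so the central
#' residue of each 12-residue helix is the conserved `x.50` anchor;
#' G-alpha and ligand residues are left unmapped.
#'
#' @param spec a [synthetic_spec()].
#' @return A [bw_map()].
#' @export
synthetic_bw_map <- function(spec) {
  m <- spec$residues_per_helix
  resid <- seq_len(spec$n_helices * m)
  h <- (resid - 1L) %/% m + 1L
  pos <- (resid - 1L) %% m + 1L
  bw_map(resid, sprintf("%d.%d", h, 50L - ceiling(m / 2) + pos))
}

#' Write a synthetic ensemble to disk
#'
#' Writes the shared topology (`topology.pdb`, canonical coordinates), one
#' multi-model PDB per trajectory and condition, a BW map and a YAML echo
#' of the specification (provenance); the layout round-trips through
#' [load_structure()].
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @param conditions condition labels to generate.
#' @return Invisibly, a manifest list of the written paths.
#' @export
write_synthetic <- function(spec, dir, conditions = c("A", "B")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  topo <- resolve_synthetic(spec)
  topo_model <- structure_model(topo$atoms,
                                matrix(as.vector(t(topo$x0)), nrow = 1))
  topo_path <- file.path(dir, "topology.pdb")
  write_models_pdb(topo_model, topo_path)
  paths <- list(topology = topo_path, trajectories = list())
  for (cond in conditions) {
    model <- generate_condition(spec, cond)
    for (tr in seq_len(nrow(model$traj_bounds))) {
      p <- file.path(dir, sprintf("cond_%s_traj_%d.pdb", cond, tr))
      write_models_pdb(model, p,
                       frames = seq(model$traj_bounds$start[tr],
                                    model$traj_bounds$end[tr]))
      paths$trajectories[[paste(cond, tr)]] <- p
    }
  }
  bw <- synthetic_bw_map(spec)
  bw_path <- file.path(dir, "bw_map.txt")
  writeLines(paste(bw$resid, bw$bw), bw_path)
  paths$bw_map <- bw_path
  echo <- spec
  echo$planted_contacts <- as.list(spec$planted_contacts)
  echo$interface_contacts <- as.list(spec$interface_contacts)
  yaml::write_yaml(unclass(echo), file.path(dir, "spec.yaml"))
  paths$spec <- file.path(dir, "spec.yaml")
  invisible(paths)
}
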