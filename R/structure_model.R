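# In-memory model of a topology plus trajectory frames for one simulated
# condition.  Coordinates are stored bio3d-style: an F x 3A matrix whose row
# f is (x1, y1, z1, x2, ...) in Angstrom.

#' Construct a structure model
#'
#' A `structure_model` bundles a topology (per-atom metadata) with the
#' coordinate frames of one simulated condition, possibly concatenated from
#' several independent trajectories.  All analysis stages of the package
#' operate on this container.
#'
#' @param atoms data.frame with one row per atom and columns `name`,
#'   `element`, `mass` (Da), `resid` (construct residue number), `resname`,
#'   `chain`.
#' @param xyz numeric matrix, frames x (3 * atoms), coordinates in Angstrom.
#' @param traj_bounds optional data.frame with columns `start`, `end`
#'   (1-based frame indices) partitioning the frames into independent
#'   trajectories; defaults to a single trajectory spanning all frames.
#' @param box optional per-frame box dimensions (frames x 3), Angstrom.
#' @param condition free-text condition label (e.g. `"dopamine-alone"`).
#'
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, xyz, traj_bounds = NULL, box = NULL,
                            condition = "") {
  atoms <- as.data.frame(atoms)
  needed <- c("name", "element", "mass", "resid", "resname", "chain")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    .stopf("atoms table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms))
    .stopf("xyz has %d columns; expected 3 x %d atoms = %d",
           ncol(xyz), nrow(atoms), 3L * nrow(atoms))
  if (!all(is.finite(xyz)))
    .stopf("non-finite coordinates in frame(s) %s",
           paste(utils::head(which(rowSums(!is.finite(xyz)) > 0), 3), collapse = ", "))
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    .stopf("atom masses must be finite and > 0")

  nf <- nrow(xyz)
  if (is.null(traj_bounds)) {
    traj_bounds <- data.frame(start = 1L, end = nf)
  }
  traj_bounds <- as.data.frame(traj_bounds)
  o <- order(traj_bounds$start)
  traj_bounds <- traj_bounds[o, , drop = FALSE]
  if (traj_bounds$start[1] != 1L || traj_bounds$end[nrow(traj_bounds)] != nf ||
      (nrow(traj_bounds) > 1 &&
       any(traj_bounds$start[-1] != traj_bounds$end[-nrow(traj_bounds)] + 1L)))
    .stopf("trajectory boundaries must partition frames 1..%d without gaps or overlap", nf)

  res_key <- paste(atoms$chain, atoms$resid, sep = ":")
  residues <- atoms[!duplicated(res_key), c("chain", "resid", "resname")]
  rownames(residues) <- NULL

  structure(
    list(atoms = atoms, residues = residues, xyz = xyz,
         traj_bounds = traj_bounds, box = box, condition = condition),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d residues, %d frames in %d trajectory(ies)\n",
              nrow(x$atoms), nrow(x$residues), nrow(x$xyz), nrow(x$traj_bounds)))
  if (nzchar(x$condition)) cat("condition:", x$condition, "\n")
  chains <- table(x$atoms$chain[!duplicated(paste(x$atoms$chain, x$atoms$resid))])
  cat("chains:", paste(sprintf("%s (%d res)", names(chains), chains), collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames / atoms in a structure model
#' @param model a [structure_model()].
#' @return integer count.
#' @export
n_frames <- function(model) nrow(model$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(model) nrow(model$atoms)

# 1-based frame index range of each independent trajectory, as a list.
.traj_frames <- function(model) {
  lapply(seq_len(nrow(model$traj_bounds)), function(i)
    seq(model$traj_bounds$start[i], model$traj_bounds$end[i]))
}

# logical per-atom heavy mask ("heavy" = element other than hydrogen)
.heavy_mask <- function(model) toupper(model$atoms$element) != "H"

#' Load a topology and trajectory frames
#'
#' Reads a PDB topology (multi-model PDB supported) and optional trajectory
#' frame files into a [structure_model()].  Each frame file is treated as
#' one independent trajectory, concatenated in argument order; when no
#' frame files are given the topology's own MODEL records form a single
#' trajectory.  Supported frame formats: multi-model PDB and DCD.
#'
#' @param topology path to a PDB file.
#' @param frames character vector of frame file paths (`.pdb` or `.dcd`),
#'   or `NULL`.
#' @param condition condition label stored on the model.
#' @return A [structure_model()].
#' @export
load_structure <- function(topology, frames = NULL, condition = "") {
  pdb <- tryCatch(
    bio3d::read.pdb(topology, multi = TRUE, verbose = FALSE),
    error = function(e) .stopf("failed to parse topology '%s': %s",
                               topology, conditionMessage(e)))
  at <- pdb$atom
  element <- at$elesy
  blank <- is.na(element) | !nzchar(trimws(element))
  element[blank] <- .infer_element(at$elety[blank])
  element <- toupper(trimws(element))
  mass <- .mass_of(element)
  if (anyNA(mass))
    .stopf("unknown element(s) in topology: %s",
           paste(unique(element[is.na(mass)]), collapse = ", "))
  atoms <- data.frame(
    name = trimws(at$elety), element = element, mass = mass,
    resid = at$resno, resname = trimws(at$resid), chain = at$chain,
    stringsAsFactors = FALSE
  )
  atoms$chain[is.na(atoms$chain)] <- "A"
  na3 <- 3L * nrow(atoms)

  if (is.null(frames) || length(frames) == 0L) {
    xyz <- matrix(pdb$xyz, ncol = na3)
    return(structure_model(atoms, xyz, condition = condition))
  }

  frame_list <- lapply(frames, function(path) {
    ext <- tolower(tools::file_ext(path))
    fx <- if (ext == "dcd") {
      as.matrix(bio3d::read.dcd(path, verbose = FALSE))
    } else if (ext %in% c("pdb", "ent")) {
      p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
      m <- as.matrix(p$xyz)
      if (is.null(dim(m))) m <- matrix(m, nrow = 1)
      m
    } else {
      .stopf("unsupported frame format '%s' for '%s' (use PDB or DCD)", ext, path)
    }
    if (ncol(fx) != na3)
      .stopf("atom count mismatch: topology has %d atoms but '%s' has %g",
             nrow(atoms), path, ncol(fx) / 3)
    fx
  })
  xyz <- do.call(rbind, frame_list)
  nfr <- vapply(frame_list, nrow, integer(1))
  ends <- cumsum(nfr)
  traj_bounds <- data.frame(start = c(1L, utils::head(ends, -1) + 1L), end = ends)
  structure_model(atoms, xyz, traj_bounds = traj_bounds, condition = condition)
}

#' Write a structure model as a multi-model PDB file
#'
#' Frames are emitted as MODEL/ENDMDL blocks at standard PDB precision
#' (0.001 Angstrom), so a write/read round trip preserves atom order and
#' names exactly and coordinates to PDB precision.
#'
#' @param model a [structure_model()].
#' @param path output file path.
#' @param frames frame indices to write (default: all).
#' @return `path`, invisibly.
#' @export
write_models_pdb <- function(model, path, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(model))
  at <- model$atoms
  nm <- ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name)
  pre <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    ",
                 seq_len(nrow(at)) %% 100000, nm,
                 substr(at$resname, 1, 3), substr(at$chain, 1, 1), at$resid)
  post <- sprintf("  1.00  0.00          %2s", substr(at$element, 1, 2))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    co <- .frame_coords(model$xyz, f)
    lines <- paste0(pre,
                    sprintf("%8.3f%8.3f%8.3f", co[, 1], co[, 2], co[, 3]),
                    post)
    writeLines(c(sprintf("MODEL     %4d", f), lines, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}
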