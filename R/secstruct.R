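# Three-state secondary structure from backbone geometry.
#
# Backbone hydrogen bonds are scored with the Kabsch-Sander electrostatic
# energy E = 27.888 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol between
# the donor's N-H and the acceptor's C=O; a bond is declared when
# E < -0.5 kcal/mol.  Amide hydrogens are reconstructed geometrically
# (1.01 Angstrom from N, opposite the preceding carbonyl), the standard
# practice for simulation frames exported without hydrogens.  Turn and
# bridge patterns then yield H/G/I helices and bridge (sheet) residues,
# collapsed to helix / sheet / coil.

KS_COUPLING <- 27.888     # q1*q2*f, kcal*Angstrom/mol
KS_HBOND_CUTOFF <- -0.5   # kcal/mol
CHAIN_BREAK_CA <- 4.5     # consecutive-residue CA-CA break distance, Angstrom

#' Kabsch-Sander hydrogen-bond energy
#'
#' @param donor list with 3-vectors `N` and `H` (amide nitrogen and
#'   hydrogen of the donor residue).
#' @param acceptor list with 3-vectors `C` and `O` (carbonyl carbon and
#'   oxygen of the acceptor residue).
#' @return Energy in kcal/mol; an H-bond is declared when the energy is
#'   below -0.5 kcal/mol.
#' @export
hbond_energy <- function(donor, acceptor) {
  r_on <- .vnorm(acceptor$O - donor$N)
  r_ch <- .vnorm(acceptor$C - donor$H)
  r_oh <- .vnorm(acceptor$O - donor$H)
  r_cn <- .vnorm(acceptor$C - donor$N)
  if (min(r_on, r_ch, r_oh, r_cn) <= 0.5) return(0)  # atom overlap: no bond
  KS_COUPLING * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

# Backbone bookkeeping for the protein residues of a model: atom row per
# residue for N, CA, C, O.  Residues missing any backbone atom are dropped
# from donation/acceptance with one logged warning.
.backbone_index <- function(model) {
  at <- model$atoms
  key <- paste(at$chain, at$resid, sep = ":")
  res <- model$residues
  res_key <- paste(res$chain, res$resid, sep = ":")
  pick <- function(name) {
    i <- which(at$name == name)
    i[match(res_key, key[i])]
  }
  bb <- data.frame(chain = res$chain, resid = res$resid, resname = res$resname,
                   N = pick("N"), CA = pick("CA"), C = pick("C"), O = pick("O"))
  is_protein <- !is.na(bb$CA) & !is.na(bb$N) & !is.na(bb$C)
  partial <- is_protein & is.na(bb$O)
  if (any(partial))
    .warnf("residue(s) missing backbone O excluded from H-bonding: %s",
           paste(bb$resid[partial], collapse = ", "))
  bb[is_protein & !is.na(bb$O), , drop = FALSE]
}

# Per-frame 3-state (or raw-letter) assignment for the backbone table bb.
.dssp_one_frame <- function(co, bb, simplify = TRUE) {
  n <- nrow(bb)
  lab <- rep(if (simplify) "coil" else "-", n)
  if (n < 5L) return(lab)

  N <- co[bb$N, , drop = FALSE]
  CA <- co[bb$CA, , drop = FALSE]
  C <- co[bb$C, , drop = FALSE]
  O <- co[bb$O, , drop = FALSE]

  # peptide link between consecutive table rows: same chain, consecutive
  # residue numbering, CA-CA within the chain-break distance
  same <- bb$chain[-n] == bb$chain[-1] & bb$resid[-1] == bb$resid[-n] + 1L
  dca <- sqrt(rowSums((CA[-1, , drop = FALSE] - CA[-n, , drop = FALSE])^2))
  linked <- same & dca <= CHAIN_BREAK_CA

  # reconstructed amide H; residues without a preceding bonded carbonyl
  # (chain starts) and prolines never donate
  H <- matrix(NA_real_, n, 3)
  can_donate <- c(FALSE, linked) & bb$resname != "PRO"
  di <- which(can_donate)
  if (length(di)) {
    dir <- C[di - 1L, , drop = FALSE] - O[di - 1L, , drop = FALSE]
    dir <- dir / sqrt(rowSums(dir^2))
    H[di, ] <- N[di, , drop = FALSE] + 1.01 * dir
  }

  # energy matrix: rows donors, cols acceptors
  r_on <- .cdist(N, O)
  r_cn <- .cdist(N, C)
  Hd <- H[di, , drop = FALSE]
  E <- matrix(0, n, n)
  if (length(di)) {
    r_ch <- .cdist(Hd, C)
    r_oh <- .cdist(Hd, O)
    r_on_d <- r_on[di, , drop = FALSE]
    r_cn_d <- r_cn[di, , drop = FALSE]
    Ed <- KS_COUPLING * (1 / r_on_d + 1 / r_ch - 1 / r_oh - 1 / r_cn_d)
    if (min(r_on_d) <= 0.5 || min(r_ch) <= 0.5 ||
        min(r_oh) <= 0.5 || min(r_cn_d) <= 0.5) {
      Ed[r_on_d <= 0.5 | r_ch <= 0.5 | r_oh <= 0.5 | r_cn_d <= 0.5] <- 0
    }
    E[di, ] <- Ed
  }
  diag(E) <- 0
  hb <- E < KS_HBOND_CUTOFF  # hb[d, a]: N-H of d bonds C=O of a

  # n-turns: H-bond CO(t) -> NH(t+k) with an unbroken chain over the span;
  # break bookkeeping via a prefix sum over broken links
  brk <- c(0, cumsum(!linked))
  turn <- function(k) {
    t <- seq_len(n - k)
    ok <- logical(n)
    ok[t] <- hb[cbind(t + k, t)] & (brk[t + k] - brk[t] == 0)
    ok
  }
  t3 <- turn(3L); t4 <- turn(4L); t5 <- turn(5L)

  mark <- function(lab, starts, len, value, overwrite) {
    for (s in starts) {
      j <- s:(s + len - 1L)
      j <- j[j <= n]
      repl <- lab[j] %in% overwrite
      lab[j[repl]] <- value
    }
    lab
  }

  # bridges (parallel / antiparallel); B and E both collapse to sheet, so
  # ladder extension cannot alter the 3-state output and is not tracked
  bridge <- logical(n)
  bonds <- which(hb, arr.ind = TRUE)
  if (nrow(bonds)) {
    interior_ok <- function(i) i > 1L & i < n & linked[pmax(i - 1L, 1L)] & linked[pmin(i, n - 1L)]
    for (r in seq_len(nrow(bonds))) {
      d <- bonds[r, 1]; a <- bonds[r, 2]
      # parallel: hb(j, i-1) & hb(i+1, j)  -> bridge(i, j)
      i <- a + 1L; j <- d
      if (i <= n - 1L && abs(i - j) >= 3L && hb[i + 1L, j] &&
          interior_ok(i) && interior_ok(j)) { bridge[i] <- TRUE; bridge[j] <- TRUE }
      # antiparallel form 1: hb(j, i) & hb(i, j) -> bridge(i, j)
      i <- a; j <- d
      if (abs(i - j) >= 3L && hb[i, j] &&
          interior_ok(i) && interior_ok(j)) { bridge[i] <- TRUE; bridge[j] <- TRUE }
      # antiparallel form 2: hb(j+1, i-1) & hb(i+1, j-1) -> bridge(i, j)
      i <- a + 1L; j <- d - 1L
      if (i <= n - 1L && j >= 2L && abs(i - j) >= 3L && hb[i + 1L, j - 1L] &&
          interior_ok(i) && interior_ok(j)) { bridge[i] <- TRUE; bridge[j] <- TRUE }
    }
  }

  raw <- rep("-", n)
  # priority (low to high): I, G, sheet, H
  s5 <- which(t5[-1] & t5[-n]) + 1L  # start positions s with turn5(s-1) & turn5(s)
  s5 <- s5[s5 <= n - 4L + 0L]
  raw <- mark(raw, s5, 5L, "I", "-")
  s3 <- which(t3[-1] & t3[-n]) + 1L
  raw <- mark(raw, s3, 3L, "G", c("-", "I"))
  raw[bridge] <- "E"
  s4 <- which(t4[-1] & t4[-n]) + 1L
  raw <- mark(raw, s4, 4L, "H", c("-", "I", "G", "E"))

  if (!simplify) return(raw)
  out <- rep("coil", n)
  out[raw %in% c("H", "G", "I")] <- "helix"
  out[raw == "E"] <- "sheet"
  out
}

#' Assign secondary structure for one frame
#'
#' Runs the turn/bridge pattern assignment on the protein residues of the
#' model (residues with complete N, CA, C, O backbones) and collapses the
#' raw states to the three broad categories helix (H, G, I), sheet (bridge)
#' and coil.  Chains shorter than five residues cannot host a four-turn
#' and come out all coil.
#'
#' @param model a [structure_model()].
#' @param frame 1-based frame index.
#' @param simplify return 3-state labels (default) or raw letters.
#' @return Character vector of labels named by `chain:resid`.
#' @export
assign_frame <- function(model, frame, simplify = TRUE) {
  if (frame < 1L || frame > n_frames(model))
    .stopf("frame %d out of range 1..%d", frame, n_frames(model))
  bb <- .backbone_index(model)
  if (nrow(bb) == 0L) .stopf("model contains no protein residues")
  co <- .frame_coords(model$xyz, frame)
  setNames(.dssp_one_frame(co, bb, simplify),
           paste(bb$chain, bb$resid, sep = ":"))
}

# label matrix (residues x frames) for a set of frames
.dssp_track <- function(model, bb, frames) {
  out <- matrix(NA_character_, nrow(bb), length(frames))
  for (k in seq_along(frames)) {
    co <- .frame_coords(model$xyz, frames[k])
    out[, k] <- .dssp_one_frame(co, bb, simplify = TRUE)
  }
  rownames(out) <- paste(bb$chain, bb$resid, sep = ":")
  out
}

#' Bootstrap helicity fractions
#'
#' Labels every pooled frame once, then estimates the per-residue fraction
#' of frames in helix over bootstrap frame samples; the reported fraction
#' is the mean over samples and the spread their standard deviation.  The
#' full per-frame label track is retained for evolution-style plots.
#'
#' @param model a [structure_model()].
#' @param residues a [selection_spec()] restricting the reported residues
#'   (the assignment itself always sees the whole protein, since H-bond
#'   partners may lie outside the selection); `NULL` reports all protein
#'   residues.
#' @param plan a [bootstrap_plan()].
#' @param bw optional [bw_map()].
#' @param chains optional chain filter for the assignment itself.  Helix
#'   labels are determined by intra-chain turn patterns, so restricting to
#'   the chain of interest is exact and cheaper; sheet labels from
#'   inter-chain bridges would be lost, which does not affect helicity.
#' @return An object of class `helicity_track`: per-residue table
#'   (`chain`, `resid`, `helix_fraction`, `sd`) plus the label track
#'   (residues x frames) and the plan.
#' @export
helicity_fractions <- function(model, residues = NULL,
                               plan = bootstrap_plan(), bw = NULL,
                               chains = NULL) {
  bb <- .backbone_index(model)
  if (!is.null(chains)) bb <- bb[bb$chain %in% chains, , drop = FALSE]
  if (nrow(bb) == 0L) .stopf("model contains no protein residues")
  nf <- n_frames(model)
  track <- .dssp_track(model, bb, seq_len(nf))
  helix <- track == "helix"
  samples <- .plan_samples(plan, nf)
  per_sample <- vapply(samples, function(idx)
    rowMeans(helix[, idx, drop = FALSE]), numeric(nrow(bb)))
  per_sample <- matrix(per_sample, nrow = nrow(bb))
  tab <- data.frame(chain = bb$chain, resid = bb$resid,
                    bw = if (!is.null(bw)) suppressWarnings(bw_index(bw, bb$resid)) else NA_character_,
                    helix_fraction = rowMeans(per_sample),
                    sd = apply(per_sample, 1, stats::sd))
  if (plan$n_samples == 1L) tab$sd <- 0
  if (!is.null(residues)) {
    keep_res <- .spec_residues(model, residues, bw)
    sel <- tab$resid %in% keep_res
    if (!is.null(residues$chain)) sel <- sel & tab$chain %in% residues$chain
    tab <- tab[sel, , drop = FALSE]
    track <- track[sel, , drop = FALSE]
    per_sample <- per_sample[sel, , drop = FALSE]
  }
  rownames(tab) <- NULL
  structure(list(fractions = tab, track = track, per_sample = per_sample,
                 plan = plan, condition = model$condition),
            class = "helicity_track")
}

#' @export
print.helicity_track <- function(x, ...) {
  cat(sprintf("helicity_track: %d residues x %d frames; condition: %s\n",
              nrow(x$track), ncol(x$track), x$condition))
  print.data.frame(utils::head(x$fractions, 8), digits = 3)
  invisible(x)
}

#' Plot a secondary-structure evolution track
#'
#' @param x a [helicity_fractions()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot.helicity_track <- function(x, ...) {
  states <- matrix(match(x$track, c("coil", "sheet", "helix")),
                   nrow(x$track))
  graphics::image(t(states), col = c("grey85", "steelblue", "firebrick"),
                  axes = FALSE, xlab = "frame", ylab = "residue", ...)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(x$track)),
                 labels = sub("^.*:", "", rownames(x$track)), las = 1, cex.axis = 0.6)
  invisible(x)
}
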