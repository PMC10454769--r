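# Least-squares superposition and the two ligand-RMSD schemes.

#' Kabsch superposition
#'
#' Finds the proper rotation (det = +1) and translation minimizing the
#' (optionally weighted) squared deviation between two paired coordinate
#' sets, via SVD of the cross-covariance matrix.
#'
#' @param mobile,reference n x 3 coordinate matrices (n >= 3, not
#'   collinear).
#' @param weights optional per-atom weights.
#' @return list with `rotation` (3 x 3), `translation` (length-3; the fit
#'   is `fitted = mobile %*% t(rotation) + translation`), `fitted`
#'   coordinates and the post-fit `rmsd`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) .stopf("coordinate counts differ")
  if (n < 3L) .stopf("need at least 3 alignment atoms")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  mu_m <- colSums(mobile * w)
  mu_r <- colSums(reference * w)
  M <- sweep(mobile, 2, mu_m)
  R0 <- sweep(reference, 2, mu_r)
  # collinearity check on both centered sets
  for (X in list(M, R0)) {
    sv <- svd(X, nu = 0, nv = 0)$d
    if (sv[2] <= 1e-8 * max(sv[1], 1e-12))
      .stopf("alignment atoms are collinear or degenerate")
  }
  Hm <- crossprod(M * w, R0)          # 3 x 3 cross-covariance
  s <- svd(Hm)
  d <- sign(det(tcrossprod(s$v, s$u)))
  Rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- sweep(M %*% t(Rot), 2, mu_r, "+")
  rmsd <- sqrt(sum(w * rowSums((fitted - sweep(R0, 2, mu_r, "+"))^2)))
  list(rotation = Rot, translation = as.numeric(mu_r - Rot %*% mu_m),
       fitted = fitted, rmsd = rmsd)
}

# RMSD of target atoms after fitting frame `f` onto reference coordinates
# on the align atoms (no re-fit on the target).
.fit_then_rmsd <- function(co_f, co_ref, align_idx, target_idx, masses = NULL) {
  fit <- kabsch_superpose(co_f[align_idx, , drop = FALSE],
                          co_ref[align_idx, , drop = FALSE])
  moved <- sweep(co_f[target_idx, , drop = FALSE] %*% t(fit$rotation),
                 2, fit$translation, "+")
  diff2 <- rowSums((moved - co_ref[target_idx, , drop = FALSE])^2)
  sqrt(mean(diff2))
}

#' Evolution RMSD of a substructure
#'
#' For each trajectory independently: every frame is aligned to that
#' trajectory's first frame on the alignment selection (conventionally
#' C-alpha atoms), then the RMSD of the target heavy atoms is computed
#' without re-fitting on the target.
#'
#' @param model a [structure_model()].
#' @param align [selection_spec()] for the alignment atoms.
#' @param target [selection_spec()] for the reported atoms (heavy atoms of
#'   a ligand, typically).
#' @param bw optional [bw_map()].
#' @return An object of class `rmsd_series`: data.frame with `trajectory`,
#'   `frame` (global index) and `rmsd` (Angstrom).
#' @export
evolution_rmsd <- function(model, align, target, bw = NULL) {
  align_idx <- resolve_selection(model, align, bw)
  target_idx <- resolve_selection(model, target, bw)
  rows <- lapply(seq_len(nrow(model$traj_bounds)), function(t) {
    frames <- seq(model$traj_bounds$start[t], model$traj_bounds$end[t])
    co_ref <- .frame_coords(model$xyz, frames[1])
    r <- vapply(frames, function(f)
      .fit_then_rmsd(.frame_coords(model$xyz, f), co_ref, align_idx, target_idx),
      numeric(1))
    data.frame(trajectory = t, frame = frames, rmsd = r)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rmsd_series", "data.frame")
  attr(out, "condition") <- model$condition
  out
}

#' @export
plot.rmsd_series <- function(x, ...) {
  graphics::plot(x$frame, x$rmsd, type = "n", xlab = "frame",
                 ylab = "RMSD (A)", ...)
  for (t in unique(x$trajectory)) {
    s <- x[x$trajectory == t, ]
    graphics::lines(s$frame, s$rmsd, col = t)
  }
  invisible(x)
}

#' Sampled average pairwise RMSD
#'
#' For each frame sample of the plan, the RMSD is computed for all frame
#' pairs within the sample (the lower-index frame of a pair is the
#' alignment reference) and averaged; the summary reports the mean of the
#' per-sample averages and the standard deviation across them.  An
#' exhaustive plan (one sample, all frames, without replacement) reduces
#' to the plain all-pairs average.
#'
#' @inheritParams evolution_rmsd
#' @param plan a [bootstrap_plan()]; `frames_per_sample >= 2` required.
#'   Pairwise RMSD conventionally uses plain random samples
#'   (`with_replacement = FALSE`).
#' @return An object of class `pairwise_rmsd`: list with `mean`, `sd`,
#'   `per_sample`, `n_samples`, `frames_per_sample`.
#' @export
pairwise_rmsd <- function(model, align, target,
                          plan = bootstrap_plan(with_replacement = FALSE),
                          bw = NULL) {
  if (plan$frames_per_sample < 2L)
    .stopf("pairwise RMSD needs frames_per_sample >= 2")
  align_idx <- resolve_selection(model, align, bw)
  target_idx <- resolve_selection(model, target, bw)
  samples <- .plan_samples(plan, n_frames(model))
  per_sample <- vapply(samples, function(idx) {
    idx <- sort(idx)
    co <- lapply(idx, function(f) .frame_coords(model$xyz, f))
    pr <- which(upper.tri(matrix(0, length(idx), length(idx))), arr.ind = TRUE)
    vals <- vapply(seq_len(nrow(pr)), function(k) {
      a <- pr[k, 1]; b <- pr[k, 2]
      .fit_then_rmsd(co[[b]], co[[a]], align_idx, target_idx)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  structure(list(mean = mean(per_sample),
                 sd = if (plan$n_samples > 1L) stats::sd(per_sample) else 0,
                 per_sample = per_sample,
                 n_samples = plan$n_samples,
                 frames_per_sample = plan$frames_per_sample),
            class = "pairwise_rmsd")
}

#' @export
print.pairwise_rmsd <- function(x, ...) {
  cat(sprintf("pairwise_rmsd: %.3f +/- %.3f A (%d samples x %d frames)\n",
              x$mean, x$sd, x$n_samples, x$frames_per_sample))
  invisible(x)
}
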