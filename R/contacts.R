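# Residue-residue contact detection and bootstrap contact-frequency
# estimation.  A contact is an inclusive heavy-atom minimum distance
# (<= cutoff, 4.5 Angstrom by convention) between two residues.  The
# receptor-internal network and the receptor/G-alpha interface analysis are
# the same operation with the two residue groups drawn from different
# chains; there is no special-cased interface path.

# Build the residue slot layout for a group pair: returns list with
# pair table (res_i/res_j metadata), CSR atom layout and slot pair matrix.
.contact_layout <- function(model, groupA, groupB = NULL, bw = NULL) {
  resA <- .spec_residues(model, groupA, bw)
  chainA <- if (!is.null(groupA$chain)) groupA$chain else NULL
  heavy <- .heavy_mask(model)
  at <- model$atoms

  grp_atoms <- function(resids, chain) {
    keep <- heavy & at$resid %in% resids
    if (!is.null(chain)) keep <- keep & at$chain %in% chain
    key <- paste(at$chain, at$resid, sep = ":")
    lv <- unique(key[keep])  # model atom order, not alphabetical
    split(which(keep), factor(key[keep], levels = lv))
  }
  slot_meta <- function(g) {
    first <- vapply(g, `[`, 0L, 1)
    list(resid = at$resid[first], chain = at$chain[first])
  }
  ga <- grp_atoms(resA, chainA)
  ma <- slot_meta(ga)
  if (is.null(groupB)) {
    slots <- ga
    np <- length(slots)
    if (np < 2L) .stopf("need at least two residues for within-group contacts")
    pr <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
    pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
    pairs <- cbind(pr[, 1] - 1L, pr[, 2] - 1L)
    tab <- data.frame(res_i = ma$resid[pr[, 1]], res_j = ma$resid[pr[, 2]],
                      chain_i = ma$chain[pr[, 1]], chain_j = ma$chain[pr[, 2]])
  } else {
    resB <- .spec_residues(model, groupB, bw)
    chainB <- if (!is.null(groupB$chain)) groupB$chain else NULL
    gb <- grp_atoms(resB, chainB)
    mb <- slot_meta(gb)
    slots <- c(ga, gb)
    nA <- length(ga); nB <- length(gb)
    pr <- expand.grid(i = seq_len(nA), j = seq_len(nB))
    same <- ma$resid[pr$i] == mb$resid[pr$j] & ma$chain[pr$i] == mb$chain[pr$j]
    pr <- pr[!same, , drop = FALSE]  # a residue is never its own contact
    pairs <- cbind(pr$i - 1L, nA + pr$j - 1L)
    tab <- data.frame(res_i = ma$resid[pr$i], res_j = mb$resid[pr$j],
                      chain_i = ma$chain[pr$i], chain_j = mb$chain[pr$j])
  }
  storage.mode(pairs) <- "integer"
  atoms0 <- unlist(slots, use.names = FALSE) - 1L
  offs <- c(0L, cumsum(vapply(slots, length, integer(1))))
  list(tab = tab, atoms0 = as.integer(atoms0), offs = as.integer(offs),
       pairs = pairs)
}

# logical n_pairs x n_frames contact matrix for the given frames
.contact_matrix <- function(model, layout, frames, cutoff) {
  xyzT <- t(model$xyz[frames, , drop = FALSE])
  pair_contact_frames(xyzT, layout$atoms0, layout$offs, layout$pairs, cutoff)
}

#' Contacts present in one frame
#'
#' @param model a [structure_model()].
#' @param frame 1-based frame index.
#' @param cutoff heavy-atom distance cutoff in Angstrom (inclusive).
#' @param groupA,groupB [selection_spec()]s naming the residue groups;
#'   `groupB = NULL` gives within-group contacts reported once as
#'   `res_i < res_j`.
#' @param bw optional [bw_map()].
#' @return data.frame of contacting pairs (`res_i`, `res_j`, `chain_i`,
#'   `chain_j`).
#' @export
frame_contacts <- function(model, frame, cutoff = 4.5,
                           groupA = selection_spec(), groupB = NULL,
                           bw = NULL) {
  if (frame < 1L || frame > n_frames(model))
    .stopf("frame %d out of range 1..%d", frame, n_frames(model))
  if (cutoff <= 0) .stopf("cutoff must be > 0")
  layout <- .contact_layout(model, groupA, groupB, bw)
  hit <- .contact_matrix(model, layout, frame, cutoff)[, 1]
  out <- layout$tab[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bootstrap contact-frequency estimation
#'
#' Per-frame contacts are computed once over the pooled frames of all
#' trajectories of the condition; each bootstrap sample then draws
#' `frames_per_sample` frames (uniformly, with replacement by default) and
#' the per-pair frequency within the sample is the fraction of drawn frames
#' in contact.  The reported frequency is the mean over samples, and the
#' reported uncertainty the standard deviation across the per-sample
#' frequencies.  A plan with one sample covering all frames without
#' replacement reduces exactly to the plain per-frame frequency.
#'
#' @inheritParams frame_contacts
#' @param plan a [bootstrap_plan()].
#' @return An object of class `contact_freqs`: pair table with columns
#'   `res_i`, `res_j`, `chain_i`, `chain_j`, `freq`, `sd`, plus the
#'   per-sample frequency matrix, cutoff and pooled frame count.
#' @export
bootstrap_frequencies <- function(model, plan = bootstrap_plan(),
                                  cutoff = 4.5, groupA = selection_spec(),
                                  groupB = NULL, bw = NULL) {
  if (cutoff <= 0) .stopf("cutoff must be > 0")
  layout <- .contact_layout(model, groupA, groupB, bw)
  nf <- n_frames(model)
  cm <- .contact_matrix(model, layout, seq_len(nf), cutoff)
  samples <- .plan_samples(plan, nf)
  per_sample <- vapply(samples, function(idx)
    rowMeans(cm[, idx, drop = FALSE]), numeric(nrow(layout$tab)))
  per_sample <- matrix(per_sample, nrow = nrow(layout$tab))
  tab <- layout$tab
  tab$freq <- rowMeans(per_sample)
  tab$sd <- apply(per_sample, 1, stats::sd)
  if (plan$n_samples == 1L) tab$sd <- 0
  structure(
    list(pairs = tab, per_sample = per_sample, cutoff = cutoff,
         plan = plan, n_frames_pooled = nf, condition = model$condition),
    class = "contact_freqs"
  )
}

#' @export
print.contact_freqs <- function(x, ...) {
  cat(sprintf("contact_freqs: %d residue pairs, cutoff %.2f A, %d pooled frames, %d sample(s)\n",
              nrow(x$pairs), x$cutoff, x$n_frames_pooled, x$plan$n_samples))
  cat(sprintf("non-zero pairs: %d; condition: %s\n",
              sum(x$pairs$freq > 0), x$condition))
  invisible(x)
}

#' Between-condition contact-frequency difference map
#'
#' Differences are `condition2 - condition1` per pair; pairs whose absolute
#' difference meets the display threshold are flagged, and pairs contacting
#' in both conditions (non-zero frequency in each) are marked.
#'
#' @param m1,m2 [bootstrap_frequencies()] results for the two conditions;
#'   they must share the residue universe and cutoff.
#' @param threshold display threshold on `|delta|` (default 0.10,
#'   inclusive).
#' @return An object of class `contact_diff`: data.frame with `freq_1`,
#'   `freq_2`, `delta`, `flagged`, `both_conditions` per pair.
#' @export
difference_map <- function(m1, m2, threshold = 0.10) {
  if (!isTRUE(all.equal(m1$cutoff, m2$cutoff)))
    .stopf("cutoff mismatch: %.3f vs %.3f", m1$cutoff, m2$cutoff)
  k1 <- paste(m1$pairs$chain_i, m1$pairs$res_i, m1$pairs$chain_j, m1$pairs$res_j)
  k2 <- paste(m2$pairs$chain_i, m2$pairs$res_i, m2$pairs$chain_j, m2$pairs$res_j)
  if (length(k1) != length(k2) || !all(k1 == k2))
    .stopf("contact matrices do not share a residue-pair universe")
  tab <- m1$pairs[, c("res_i", "res_j", "chain_i", "chain_j")]
  tab$freq_1 <- m1$pairs$freq
  tab$freq_2 <- m2$pairs$freq
  tab$delta <- tab$freq_2 - tab$freq_1
  tab$flagged <- abs(tab$delta) >= threshold
  tab$both_conditions <- tab$freq_1 > 0 & tab$freq_2 > 0
  structure(list(pairs = tab, threshold = threshold, cutoff = m1$cutoff,
                 condition_1 = m1$condition, condition_2 = m2$condition),
            class = "contact_diff")
}

#' @export
print.contact_diff <- function(x, ...) {
  cat(sprintf("contact_diff: %s vs %s, %d pairs, |delta| >= %.2f: %d flagged\n",
              x$condition_1, x$condition_2, nrow(x$pairs), x$threshold,
              sum(x$pairs$flagged)))
  invisible(x)
}

#' @export
as.data.frame.contact_diff <- function(x, ...) x$pairs

#' @export
as.data.frame.contact_freqs <- function(x, ...) x$pairs
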