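# Center-of-mass distance analysis between transmembrane subsegments
# ("protein interaction analyzer" scheme): each subsegment's mass-weighted
# heavy-atom COM is tracked per frame and the pairwise COM-COM distances
# averaged over bootstrap frame samples; two conditions are compared by a
# per-pair difference table.

#' Named residue-range subsegments
#'
#' @param ranges named list; each element an integer vector of construct
#'   residue ids (e.g. `list("1e" = 21:27)`).  Ranges must be non-empty
#'   and non-overlapping.
#' @param chain optional chain restriction applied when resolving.
#' @return An object of class `subsegment_set`.
#' @export
subsegment_set <- function(ranges, chain = NULL) {
  if (is.null(names(ranges)) || any(!nzchar(names(ranges))))
    .stopf("all subsegments must be named")
  if (any(vapply(ranges, length, integer(1)) == 0L))
    .stopf("empty subsegment range")
  all_res <- unlist(ranges)
  if (anyDuplicated(all_res))
    .stopf("subsegment ranges overlap at residue(s): %s",
           paste(unique(all_res[duplicated(all_res)]), collapse = ", "))
  structure(list(ranges = lapply(ranges, as.integer), chain = chain),
            class = "subsegment_set")
}

#' @export
print.subsegment_set <- function(x, ...) {
  cat(sprintf("subsegment_set: %d segments (%s)\n", length(x$ranges),
              paste(names(x$ranges), collapse = ", ")))
  invisible(x)
}

#' The 21 published D1R transmembrane subsegments
#'
#' Residue ranges defining the extracellular (e), middle (m) and
#' intracellular (i) thirds of the seven TM helices of the dopamine D1
#' receptor construct, including the extended intracellular portion of
#' TM5 (`5iL`) characteristic of Gs-coupled receptors.
#'
#' @return A [subsegment_set()].
#' @export
d1r_subsegments <- function() {
  subsegment_set(list(
    "1e" = 21:27,  "1m" = 28:36,  "1i" = 37:50,
    "2i" = 58:71,  "2m" = 72:80,  "2e" = 81:86,
    "3e" = 93:106, "3m" = 107:111, "3i" = 112:126,
    "4i" = 137:147, "4m" = 148:153, "4e" = 154:160,
    "5e" = 192:201, "5m" = 202:206, "5i" = 207:219, "5iL" = 220:242,
    "6i" = 267:280, "6m" = 281:285, "6e" = 286:297,
    "7e" = 310:321, "7i" = 322:332
  ))
}

#' Bootstrap COM-COM subsegment distance table
#'
#' Per sampled frame, the mass-weighted center of mass over all heavy
#' atoms of each subsegment's residues is computed; each bootstrap sample
#' contributes the mean distance over its frames, and the table reports
#' the mean and standard deviation across samples for every subsegment
#' pair.
#'
#' @param model a [structure_model()].
#' @param segs a [subsegment_set()].
#' @param plan a [bootstrap_plan()].
#' @return An object of class `pia_table`: data.frame `seg_i`, `seg_j`,
#'   `mean_dist`, `sd` plus the per-sample distance matrix.
#' @export
pia_distances <- function(model, segs, plan = bootstrap_plan()) {
  at <- model$atoms
  heavy <- .heavy_mask(model)
  idx_list <- lapply(segs$ranges, function(r) {
    keep <- heavy & at$resid %in% r
    if (!is.null(segs$chain)) keep <- keep & at$chain %in% segs$chain
    idx <- which(keep)
    idx
  })
  empty <- vapply(idx_list, length, integer(1)) == 0L
  if (any(empty))
    .stopf("subsegment(s) resolve to zero atoms: %s",
           paste(names(idx_list)[empty], collapse = ", "))

  nf <- n_frames(model)
  ns <- length(idx_list)
  # per-frame COMs: frames x 3 per segment, by weighted column sums
  coms <- lapply(idx_list, function(idx) {
    w <- at$mass[idx] / sum(at$mass[idx])
    cbind(model$xyz[, 3 * idx - 2, drop = FALSE] %*% w,
          model$xyz[, 3 * idx - 1, drop = FALSE] %*% w,
          model$xyz[, 3 * idx, drop = FALSE] %*% w)
  })
  pr <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  # distances: pairs x frames
  dists <- t(vapply(seq_len(nrow(pr)), function(k) {
    d <- coms[[pr[k, 1]]] - coms[[pr[k, 2]]]
    sqrt(rowSums(d * d))
  }, numeric(nf)))

  samples <- .plan_samples(plan, nf)
  per_sample <- vapply(samples, function(idx)
    rowMeans(dists[, idx, drop = FALSE]), numeric(nrow(pr)))
  per_sample <- matrix(per_sample, nrow = nrow(pr))
  nm <- names(idx_list)
  tab <- data.frame(seg_i = nm[pr[, 1]], seg_j = nm[pr[, 2]],
                    mean_dist = rowMeans(per_sample),
                    sd = apply(per_sample, 1, stats::sd))
  if (plan$n_samples == 1L) tab$sd <- 0
  structure(list(table = tab, per_sample = per_sample, plan = plan,
                 condition = model$condition),
            class = "pia_table")
}

#' @export
print.pia_table <- function(x, ...) {
  cat(sprintf("pia_table: %d subsegment pairs; condition: %s\n",
              nrow(x$table), x$condition))
  print.data.frame(utils::head(x$table, 8), digits = 4)
  invisible(x)
}

#' Between-condition COM-COM distance differences
#'
#' @param t1,t2 [pia_distances()] results for condition 1 and 2 over the
#'   same subsegment set.
#' @return data.frame with `seg_i`, `seg_j`, `dist_1`, `dist_2`, `delta`
#'   (`condition2 - condition1`, Angstrom).
#' @export
pia_difference <- function(t1, t2) {
  k1 <- paste(t1$table$seg_i, t1$table$seg_j)
  k2 <- paste(t2$table$seg_i, t2$table$seg_j)
  if (length(k1) != length(k2) || !all(k1 == k2))
    .stopf("subsegment sets differ between conditions")
  data.frame(seg_i = t1$table$seg_i, seg_j = t1$table$seg_j,
             dist_1 = t1$table$mean_dist, dist_2 = t2$table$mean_dist,
             delta = t2$table$mean_dist - t1$table$mean_dist)
}
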