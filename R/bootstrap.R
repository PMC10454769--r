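# Frame-resampling plans shared by the contact, helicity, RMSD and COM
# distance stages.

#' Bootstrap sampling plan
#'
#' Describes how frames are resampled from the pooled frames of all
#' trajectories of a condition.  The default (10 samples of 2000 frames,
#' with replacement) is the plan used for contact-frequency, helicity and
#' subsegment-distance estimation; pairwise-RMSD estimation conventionally
#' uses plain random samples (`with_replacement = FALSE`).
#'
#' @param n_samples number of resampled frame sets (>= 1).
#' @param frames_per_sample frames drawn per set (>= 1).
#' @param with_replacement draw with replacement (bootstrap) or without
#'   (plain random sample).
#' @param seed integer seed; per-sample sub-seeds are derived
#'   deterministically so any sample can be reproduced independently.
#' @return An object of class `bootstrap_plan`.
#' @export
bootstrap_plan <- function(n_samples = 10L, frames_per_sample = 2000L,
                           with_replacement = TRUE, seed = 1L) {
  n_samples <- as.integer(n_samples)
  frames_per_sample <- as.integer(frames_per_sample)
  if (n_samples < 1L || frames_per_sample < 1L)
    .stopf("n_samples and frames_per_sample must be >= 1")
  structure(list(n_samples = n_samples, frames_per_sample = frames_per_sample,
                 with_replacement = isTRUE(with_replacement),
                 seed = as.integer(seed)),
            class = "bootstrap_plan")
}

#' @export
print.bootstrap_plan <- function(x, ...) {
  cat(sprintf("bootstrap_plan: %d x %d frames, %s replacement, seed %d\n",
              x$n_samples, x$frames_per_sample,
              if (x$with_replacement) "with" else "without", x$seed))
  invisible(x)
}

# frame index sets for each sample of a plan, drawn from n_frames pooled
# frames; deterministic per (plan$seed, sample index)
.plan_samples <- function(plan, n_frames) {
  if (n_frames < 1L) .stopf("no pooled frames to sample from")
  if (!plan$with_replacement && plan$frames_per_sample > n_frames)
    .stopf("cannot draw %d frames without replacement from %d",
           plan$frames_per_sample, n_frames)
  lapply(seq_len(plan$n_samples), function(s) {
    .with_seed(.sub_seed(plan$seed, paste0("sample:", s)), {
      sample.int(n_frames, plan$frames_per_sample,
                 replace = plan$with_replacement)
    })
  })
}
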