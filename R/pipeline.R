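# Two-condition comparison pipeline: contacts -> network -> secondary
# structure -> interface -> subsegment distances -> ligand RMSD, from one
# configuration, with deterministic seed fan-out per stage.

#' Analysis configuration for a two-condition comparison
#'
#' @param condition_1,condition_2 each either a [structure_model()], a
#'   [synthetic_spec()] (generated as condition `"A"`/`"B"` respectively),
#'   or a list `list(topology =, frames =, condition =)` of file paths for
#'   [load_structure()].
#' @param cutoff contact cutoff in Angstrom.
#' @param plan bootstrap plan template; each stage derives its own seeded
#'   copy from `seed`.
#' @param highlight centrality highlight threshold (absolute score
#'   difference, strictly exceeded).
#' @param contact_threshold display threshold for contact-frequency
#'   differences (inclusive).
#' @param min_score centrality table filter (`NULL` keeps all residues).
#' @param helicity_threshold display threshold for helicity-fraction
#'   differences (inclusive).
#' @param receptor_chain,galpha_chain chain ids of the receptor and the
#'   G-alpha subunit (`NULL` disables the interface stage).
#' @param helicity_residues [selection_spec()] for the reported loop
#'   residues (`NULL` reports all protein residues).
#' @param segments [subsegment_set()] for COM-COM distances (`NULL`
#'   disables the stage).
#' @param ligand,align [selection_spec()]s for ligand RMSD (`NULL`
#'   disables the stage).
#' @param bw optional [bw_map()].
#' @param min_sequence_gap residue-graph sequence gap.
#' @param stages character vector of stages to run, a subset of
#'   `c("contacts", "network", "helicity", "interface", "pia", "rmsd")`.
#' @param seed master seed fanned out to every stage.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(condition_1, condition_2,
                            cutoff = 4.5,
                            plan = bootstrap_plan(),
                            highlight = 0.005,
                            contact_threshold = 0.10,
                            min_score = NULL,
                            helicity_threshold = 0.10,
                            receptor_chain = "R", galpha_chain = "G",
                            helicity_residues = NULL,
                            segments = NULL,
                            ligand = NULL, align = NULL,
                            bw = NULL, min_sequence_gap = 2L,
                            stages = c("contacts", "network", "helicity",
                                       "interface", "pia", "rmsd"),
                            seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(cutoff > 0, highlight >= 0, contact_threshold >= 0,
            helicity_threshold >= 0)
  structure(list(condition_1 = condition_1, condition_2 = condition_2,
                 cutoff = cutoff, plan = plan, highlight = highlight,
                 contact_threshold = contact_threshold, min_score = min_score,
                 helicity_threshold = helicity_threshold,
                 receptor_chain = receptor_chain, galpha_chain = galpha_chain,
                 helicity_residues = helicity_residues, segments = segments,
                 ligand = ligand, align = align, bw = bw,
                 min_sequence_gap = as.integer(min_sequence_gap),
                 stages = stages, seed = as.integer(seed)),
            class = "analysis_config")
}

.load_condition <- function(x, which) {
  if (inherits(x, "structure_model")) return(x)
  if (inherits(x, "synthetic_spec"))
    return(generate_condition(x, if (which == 1L) "A" else "B"))
  if (is.list(x) && !is.null(x$topology))
    return(load_structure(x$topology, x$frames,
                          condition = x$condition %||% sprintf("condition_%d", which)))
  .stopf("condition %d is neither a model, a synthetic spec nor file paths", which)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stage-specific plan: same shape as the template, seeded from the master
# seed.  Both conditions of a stage share the seed (common random numbers),
# so identical condition inputs yield identically zero difference tables.
.stage_plan <- function(config, stage, with_replacement = NULL) {
  p <- config$plan
  bootstrap_plan(p$n_samples, p$frames_per_sample,
                 with_replacement %||% p$with_replacement,
                 seed = .sub_seed(config$seed, stage))
}

#' Run the full two-condition comparison
#'
#' Executes the configured stages on both conditions and assembles the
#' comparison tables: the centrality table (per-residue scores, signed and
#' absolute differences, highlight flags), the receptor contact and
#' receptor/G-alpha interface difference maps, per-residue helicity
#' differences, the subsegment COM-COM distance difference table and
#' ligand RMSD summaries.  A stage failure aborts the run naming the
#' stage.  Reruns with the same configuration are bit-identical.
#'
#' @param config an [analysis_config()].
#' @return An object of class `allopath_report` (list of stage tables plus
#'   a `manifest` recording seeds, thresholds and versions).
#' @export
run_comparison <- function(config) {
  m1 <- .load_condition(config$condition_1, 1L)
  m2 <- .load_condition(config$condition_2, 2L)
  report <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  rec_spec <- selection_spec(chain = config$receptor_chain)

  cf1 <- cf2 <- NULL
  if (any(c("contacts", "network") %in% config$stages)) {
    cf1 <- stage("contacts", bootstrap_frequencies(
      m1, .stage_plan(config, "contacts"), config$cutoff, rec_spec, bw = config$bw))
    cf2 <- stage("contacts", bootstrap_frequencies(
      m2, .stage_plan(config, "contacts"), config$cutoff, rec_spec, bw = config$bw))
    if ("contacts" %in% config$stages)
      report$contact_difference <- stage("contacts",
        difference_map(cf1, cf2, config$contact_threshold))
  }

  if ("network" %in% config$stages) {
    report$centrality <- stage("network", {
      g1 <- build_graph(cf1, config$min_sequence_gap)
      g2 <- build_graph(cf2, config$min_sequence_gap)
      compare_conditions(eigenvector_centrality(g1), eigenvector_centrality(g2),
                         highlight = config$highlight,
                         min_score = config$min_score, bw = config$bw)
    })
  }

  if ("helicity" %in% config$stages) {
    report$helicity <- stage("helicity", {
      h1 <- helicity_fractions(m1, config$helicity_residues,
                               .stage_plan(config, "helicity"), bw = config$bw,
                               chains = config$receptor_chain)
      h2 <- helicity_fractions(m2, config$helicity_residues,
                               .stage_plan(config, "helicity"), bw = config$bw,
                               chains = config$receptor_chain)
      tab <- h1$fractions
      names(tab)[names(tab) == "helix_fraction"] <- "fraction_1"
      names(tab)[names(tab) == "sd"] <- "sd_1"
      tab$fraction_2 <- h2$fractions$helix_fraction
      tab$sd_2 <- h2$fractions$sd
      tab$delta <- tab$fraction_2 - tab$fraction_1
      tab$flagged <- abs(tab$delta) >= config$helicity_threshold
      tab
    })
  }

  if ("interface" %in% config$stages && !is.null(config$galpha_chain)) {
    report$interface_difference <- stage("interface", {
      gal_spec <- selection_spec(chain = config$galpha_chain)
      i1 <- bootstrap_frequencies(m1, .stage_plan(config, "interface"),
                                  config$cutoff, rec_spec, gal_spec, bw = config$bw)
      i2 <- bootstrap_frequencies(m2, .stage_plan(config, "interface"),
                                  config$cutoff, rec_spec, gal_spec, bw = config$bw)
      difference_map(i1, i2, config$contact_threshold)
    })
  }

  if ("pia" %in% config$stages && !is.null(config$segments)) {
    report$pia_difference <- stage("pia", {
      p1 <- pia_distances(m1, config$segments, .stage_plan(config, "pia"))
      p2 <- pia_distances(m2, config$segments, .stage_plan(config, "pia"))
      pia_difference(p1, p2)
    })
  }

  if ("rmsd" %in% config$stages && !is.null(config$ligand) &&
      !is.null(config$align)) {
    report$rmsd <- stage("rmsd", {
      list(
        evolution_1 = evolution_rmsd(m1, config$align, config$ligand, config$bw),
        evolution_2 = evolution_rmsd(m2, config$align, config$ligand, config$bw),
        pairwise_1 = pairwise_rmsd(m1, config$align, config$ligand,
                                   .stage_plan(config, "rmsd", FALSE), config$bw),
        pairwise_2 = pairwise_rmsd(m2, config$align, config$ligand,
                                   .stage_plan(config, "rmsd", FALSE), config$bw))
    })
  }

  report$manifest <- list(
    package = "allopath",
    version = as.character(utils::packageVersion("allopath")),
    seed = config$seed, cutoff = config$cutoff,
    thresholds = list(centrality_highlight = config$highlight,
                      contact_display = config$contact_threshold,
                      helicity_display = config$helicity_threshold,
                      min_score = config$min_score),
    plan = unclass(config$plan),
    stages = config$stages,
    conditions = c(m1$condition, m2$condition),
    frames = c(n_frames(m1), n_frames(m2)))
  class(report) <- "allopath_report"
  report
}

#' @export
print.allopath_report <- function(x, ...) {
  cat("allopath_report with tables:",
      paste(setdiff(names(x), "manifest"), collapse = ", "), "\n")
  if (!is.null(x$centrality))
    cat(sprintf("  centrality: %d residues, %d highlighted\n",
                nrow(x$centrality), sum(x$centrality$highlighted)))
  if (!is.null(x$interface_difference))
    cat(sprintf("  interface: %d pairs flagged\n",
                sum(x$interface_difference$pairs$flagged)))
  if (!is.null(x$helicity))
    cat(sprintf("  helicity: %d residues flagged\n", sum(x$helicity$flagged)))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits one CSV per stage table plus a JSON manifest.  Output is
#' deterministic: rerunning the same configuration reproduces the files
#' byte for byte.
#'
#' @param report a [run_comparison()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(tab, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(tab, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(report$centrality)) emit(as.data.frame(report$centrality), "centrality")
  if (!is.null(report$contact_difference))
    emit(report$contact_difference$pairs, "contact_difference")
  if (!is.null(report$interface_difference))
    emit(report$interface_difference$pairs, "interface_difference")
  if (!is.null(report$helicity)) emit(report$helicity, "helicity")
  if (!is.null(report$pia_difference)) emit(report$pia_difference, "pia_difference")
  if (!is.null(report$rmsd)) {
    emit(report$rmsd$evolution_1, "rmsd_evolution_1")
    emit(report$rmsd$evolution_2, "rmsd_evolution_2")
    pw <- data.frame(condition = 1:2,
                     mean = c(report$rmsd$pairwise_1$mean, report$rmsd$pairwise_2$mean),
                     sd = c(report$rmsd$pairwise_1$sd, report$rmsd$pairwise_2$sd))
    emit(pw, "rmsd_pairwise")
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(report$manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, mp))
}
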