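# Ballesteros-Weinstein numbering side table and residue/atom selections.

#' Ballesteros-Weinstein numbering map
#'
#' Maps construct residue numbers to Ballesteros-Weinstein (BW) indices
#' (e.g. `"3.52"`) or loop labels (e.g. `"IL2"`).  Construct residue
#' numbers remain the primary key throughout the package; BW indices are a
#' side table used for selection convenience and reporting.
#'
#' @param resid integer vector of construct residue numbers.
#' @param bw character vector of BW indices, same length.
#' @return An object of class `bw_map`.
#' @export
bw_map <- function(resid, bw) {
  resid <- as.integer(resid)
  bw <- as.character(bw)
  if (length(resid) != length(bw)) .stopf("resid and bw lengths differ")
  if (anyDuplicated(resid)) .stopf("duplicate construct residue ids in BW map")
  tm <- grepl("^[0-9]+\\.[0-9]+$", bw)
  if (anyDuplicated(bw[tm]))
    .stopf("BW map is not injective on TM indices: %s",
           paste(unique(bw[tm][duplicated(bw[tm])]), collapse = ", "))
  structure(list(resid = resid, bw = bw), class = "bw_map")
}

#' Read a BW map from a two-column text file
#'
#' @param path whitespace- or comma-separated file with columns
#'   `residue_id bw_index` (a header line is tolerated).
#' @return A [bw_map()].
#' @export
read_bw_map <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt)) & !startsWith(trimws(txt), "#")]
  parts <- strsplit(trimws(txt), "[,[:space:]]+")
  bad <- vapply(parts, length, integer(1)) < 2
  if (any(bad)) .stopf("malformed BW map line(s): %s",
                       paste(which(bad), collapse = ", "))
  first <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1)))
  if (is.na(first[1])) { parts <- parts[-1]; first <- first[-1] }  # header
  if (anyNA(first)) .stopf("non-integer residue id in BW map")
  bw_map(first, vapply(parts, `[[`, "", 2))
}

#' Look up BW indices for construct residues
#'
#' Unmapped residues are a reported miss (warning + `NA`), never a silent
#' default.
#'
#' @param map a [bw_map()].
#' @param resid construct residue numbers.
#' @return character vector of BW indices.
#' @export
bw_index <- function(map, resid) {
  i <- match(as.integer(resid), map$resid)
  if (anyNA(i))
    .warnf("no BW index for residue(s): %s",
           paste(resid[is.na(i)], collapse = ", "))
  map$bw[i]
}

#' @rdname bw_index
#' @param bw BW index strings to translate back to construct residues.
#' @export
bw_resid <- function(map, bw) {
  i <- match(as.character(bw), map$bw)
  if (anyNA(i))
    .warnf("BW index not in map: %s", paste(bw[is.na(i)], collapse = ", "))
  map$resid[i]
}

#' Residue/atom selection specification
#'
#' Selects residues by explicit construct ids, by a BW index range
#' (resolved through a [bw_map()] to the contiguous construct range between
#' the two anchors, so loop residues in between are included), and/or by
#' chain, then filters atoms.
#'
#' @param residues integer vector of construct residue ids (ranges welcome,
#'   e.g. `112:150`), or `NULL`.
#' @param bw_range string `"3.41-4.52"` naming two BW anchors, or `NULL`.
#' @param atom_filter one of `"heavy"` (all non-hydrogen atoms), `"calpha"`,
#'   `"backbone"` (N, CA, C, O).
#' @param chain chain id filter, or `NULL` for all chains.
#' @return An object of class `selection_spec`.
#' @export
selection_spec <- function(residues = NULL, bw_range = NULL,
                           atom_filter = c("heavy", "calpha", "backbone"),
                           chain = NULL) {
  atom_filter <- match.arg(atom_filter)
  if (!is.null(residues)) residues <- as.integer(residues)
  structure(list(residues = residues, bw_range = bw_range,
                 atom_filter = atom_filter, chain = chain),
            class = "selection_spec")
}

#' @export
print.selection_spec <- function(x, ...) {
  cat("selection_spec:",
      if (!is.null(x$residues)) sprintf("%d residue id(s)", length(x$residues)) else "",
      if (!is.null(x$bw_range)) sprintf("BW %s", x$bw_range) else "",
      sprintf("[%s]", x$atom_filter),
      if (!is.null(x$chain)) sprintf("chain %s", x$chain) else "", "\n")
  invisible(x)
}

# residue ids selected by a spec against a model (construct ids, sorted)
.spec_residues <- function(model, spec, bw = NULL) {
  res <- model$residues
  keep <- rep(TRUE, nrow(res))
  if (!is.null(spec$chain)) keep <- keep & res$chain %in% spec$chain
  wanted <- NULL
  if (!is.null(spec$residues)) wanted <- spec$residues
  if (!is.null(spec$bw_range)) {
    if (is.null(bw)) .stopf("selection uses a BW range but no BW map was given")
    anchors <- trimws(strsplit(spec$bw_range, "[-–]")[[1]])
    if (length(anchors) != 2) .stopf("malformed BW range '%s'", spec$bw_range)
    hit <- match(anchors, bw$bw)
    if (anyNA(hit))
      .stopf("BW index absent from map: %s",
             paste(anchors[is.na(hit)], collapse = ", "))
    lo <- min(bw$resid[hit]); hi <- max(bw$resid[hit])
    wanted <- sort(unique(c(wanted, lo:hi)))
  }
  if (!is.null(wanted)) {
    present <- wanted %in% res$resid[keep]
    if (!all(present))
      .stopf("selection references residue(s) absent from model: %s",
             paste(wanted[!present], collapse = ", "))
    keep <- keep & res$resid %in% wanted
  }
  sort(unique(res$resid[keep]))
}

#' Resolve a selection to atom indices
#'
#' @param model a [structure_model()].
#' @param spec a [selection_spec()].
#' @param bw optional [bw_map()] (required when `spec` uses a BW range).
#' @return Sorted, unique 1-based atom row indices into `model$atoms`.  The
#'   `"calpha"` filter yields exactly one atom per selected residue.
#' @export
resolve_selection <- function(model, spec, bw = NULL) {
  resids <- .spec_residues(model, spec, bw)
  at <- model$atoms
  keep <- at$resid %in% resids
  if (!is.null(spec$chain)) keep <- keep & at$chain %in% spec$chain
  keep <- keep & switch(spec$atom_filter,
    heavy = .heavy_mask(model),
    calpha = at$name == "CA",
    backbone = at$name %in% c("N", "CA", "C", "O"))
  idx <- sort(unique(which(keep)))
  if (length(idx) == 0L) .stopf("selection resolves to zero atoms")
  if (spec$atom_filter == "calpha") {
    got <- unique(at$resid[idx])
    if (length(idx) != length(got))
      .stopf("calpha filter did not yield one atom per residue")
  }
  idx
}

#' Ligand-binding pocket selection across conditions
#'
#' Returns the union, over all given condition models and all their frames,
#' of residues having any heavy atom within `cutoff` (inclusive) of any
#' ligand heavy atom, as a C-alpha selection.  This mirrors the convention
#' of aligning on pocket residues defined "in any condition".
#'
#' @param models list of [structure_model()] objects (one per condition).
#' @param ligand a [selection_spec()] resolving to the ligand's heavy atoms
#'   in every model.
#' @param cutoff distance cutoff in Angstrom (> 0 required for a non-empty
#'   pocket; `cutoff = 0` yields an empty selection).
#' @param bw optional [bw_map()] used to resolve `ligand`.
#' @return A [selection_spec()] with explicit residue ids and the
#'   `"calpha"` atom filter.
#' @export
pocket_selection <- function(models, ligand, cutoff = 4.5, bw = NULL) {
  if (inherits(models, "structure_model")) models <- list(models)
  if (cutoff < 0) .stopf("cutoff must be >= 0")
  pocket <- integer(0)
  for (m in seq_along(models)) {
    model <- models[[m]]
    lig_idx <- tryCatch(resolve_selection(model, ligand, bw),
      error = function(e) .stopf("ligand absent from condition '%s': %s",
                                 model$condition, conditionMessage(e)))
    lig_res <- unique(paste(model$atoms$chain[lig_idx], model$atoms$resid[lig_idx]))
    heavy <- which(.heavy_mask(model))
    res_key <- paste(model$atoms$chain, model$atoms$resid)
    cand <- heavy[!(res_key[heavy] %in% lig_res)]
    if (cutoff == 0 || length(cand) == 0L) next
    groups <- split(cand, res_key[cand])
    hit <- .contact_any_frame(model, groups, lig_idx, cutoff)
    pocket_res <- unique(model$atoms$resid[vapply(groups[hit], `[`, 0L, 1)])
    pocket <- union(pocket, pocket_res)
  }
  selection_spec(residues = sort(pocket), atom_filter = "calpha")
}

# residues (atom-index groups) with any heavy atom within cutoff of the
# reference atom set in any frame; returns logical per group
.contact_any_frame <- function(model, groups, ref_idx, cutoff) {
  slots <- c(groups, list(.ref = ref_idx))
  atoms0 <- unlist(slots, use.names = FALSE) - 1L
  offs <- c(0L, cumsum(vapply(slots, length, integer(1))))
  ng <- length(groups)
  pairs <- cbind(seq_len(ng) - 1L, ng)  # each group vs the reference slot
  hits <- pair_contact_frames(t(model$xyz), atoms0, offs,
                              pairs, cutoff)
  rowSums(hits) > 0
}
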