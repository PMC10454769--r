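# Published reference data shipped with the package.

#' Published D1R/dopamine eigenvector-centrality table
#'
#' The normalized eigenvector centrality scores reported for the dopamine
#' D1 receptor simulated with dopamine alone (`score_no_pam`) and with the
#' positive allosteric modulator LY3154207 bound (`score_pam`), restricted
#' to residues scoring at least 0.10 in either condition, together with
#' the published signed (`no PAM - PAM`) and absolute differences.  Useful
#' as a worked example for [compare_conditions()] and as a consistency
#' check of the table arithmetic.
#'
#' @return data.frame with columns `residue`, `bw`, `score_no_pam`,
#'   `score_pam`, `diff`, `abs_diff`.
#' @export
d1r_centrality_reference <- function() {
  utils::read.csv(system.file("extdata", "d1r_dopamine_centrality.csv",
                              package = "allopath"))
}
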