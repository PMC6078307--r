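# Bundled reference association table.
#
# inst/extdata/reward_associations.tsv transcribes, row by row, the
# published association tables of a 63-subject healthy cohort relating
# fecal indole metabolites (indole, skatole, indoleacetic acid), clinical
# scores (BMI, YFAS food addiction, HAD anxiety) and centrality metrics of
# the extended reward network (amygdala-NAcc and amygdala-anterior-insula
# circuits). Values printed as upper bounds ("< 0.001", "< 0.050") are
# stored as the bound with a companion `*_lt` flag.

#' Reference reward-network association table
#'
#' @return A data.frame of association records: `circuit`, `block_a`,
#'   `variable_a`, `block_b`, `variable_b`, `modality`, `r`, `p`, `p_lt`,
#'   `q`, `q_lt`, `df`. Variable labels follow the `metric_hemi_region`
#'   scheme (e.g. `B_R_NAcc`, betweenness of the right nucleus accumbens).
#' @examples
#' head(reward_associations())
#' @export
reward_associations <- function() {
  path <- system.file("extdata", "reward_associations.tsv", package = "bgmnet")
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  df$p_lt <- as.logical(df$p_lt)
  df$q_lt <- as.logical(df$q_lt)
  df
}

#' Tripartite network of the reference association table
#'
#' Feeds every printed row of the reference tables into [build_network()]
#' (duplicated rows across the two circuits collapse to one edge).
#'
#' @param mode,alpha Threshold mode and level; the published visualization
#'   includes all p < 0.05 associations.
#' @return A `tripartite_network`.
#' @export
reference_reward_network <- function(mode = "p", alpha = 0.05) {
  build_network(reward_associations(), mode = mode, alpha = alpha)
}

#' Direct/indirect effects implied by the reference tables
#'
#' Builds the reference network, extracts the metabolite first-neighbor
#' subnetwork, and classifies each metabolite-clinical pair.
#'
#' @inheritParams reference_reward_network
#' @return The [classify_effects()] data.frame.
#' @examples
#' reference_effects()
#' @export
reference_effects <- function(mode = "p", alpha = 0.05) {
  classify_effects(metabolite_first_neighbors(
    reference_reward_network(mode, alpha)))
}
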