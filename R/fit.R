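# Central model-fitting interface: the covariate-adjusted tripartite
# association analysis, packaged as a classed fit with methods.

#' Fit the tripartite brain-gut-metabolite association model
#'
#' The estimator is the full set of covariate-adjusted (age, sex) partial
#' Spearman correlations between the three data blocks — fecal indole
#' metabolites, clinical scores, brain-network centrality metrics — with
#' Benjamini-Hochberg q-values within families, assembled into two
#' association networks (visualization network at p < alpha, significant
#' network at q < alpha), the metabolite first-neighbor subnetwork, and the
#' direct/indirect classification of each metabolite-clinical pair.
#'
#' Given a simulated cohort, the connectome and metric stages are run first
#' (`functional_network()` at the configured z-threshold,
#' `anatomical_network()` under the configured volume normalization,
#' [metrics_table()]).
#'
#' @param x A `bgm_blocks` object (from [make_blocks()] or
#'   [simulate_blocks()]) or a `bgm_cohort` (from [simulate_cohort()]).
#' @param ... Passed between methods.
#' @return An object of class `tripartite`; see [print.tripartite()].
#' @examples
#' sp <- cohort_spec(seed = 5, n_regions = 20,
#'                   effects = list(list(a = "Skatole", b = "YFAS", rho = 0.5)))
#' fit <- tripartite(simulate_blocks(sp))
#' fit
#' summary(fit)
#' @export
tripartite <- function(x, ...) UseMethod("tripartite")

#' @rdname tripartite
#' @param alpha Significance level for thresholds and flags.
#' @param family FDR family partition; see [block_correlations()].
#' @export
tripartite.bgm_blocks <- function(x, alpha = 0.05,
                                  family = "block_pair_modality", ...) {
  records <- block_correlations(x, family_key = family, alpha = alpha)
  network <- build_network(records, mode = "p", alpha = alpha)
  network_q <- build_network(records, mode = "q", alpha = alpha)
  neighborhood <- metabolite_first_neighbors(network)
  effects <- classify_effects(neighborhood)
  structure(list(records = records,
                 table = assemble_results_table(records, alpha),
                 network = network, network_q = network_q,
                 neighborhood = neighborhood, effects = effects,
                 alpha = alpha, family = family,
                 n_subjects = length(x$subject_id),
                 call = match.call()),
            class = "tripartite")
}

#' @rdname tripartite
#' @param z_threshold Functional edge retention threshold (Fisher z scale).
#' @param anat_norm Anatomical volume normalization convention.
#' @param distance Edge-distance transform for betweenness.
#' @export
tripartite.bgm_cohort <- function(x, z_threshold = 0.3, anat_norm = "sum",
                                  distance = "inverse", ...) {
  nets <- build_connectomes(x, z_threshold = z_threshold, anat_norm = anat_norm)
  mt <- metrics_table(nets, x$regions, distance = distance)
  blocks <- make_blocks(x$subjects, mt)
  fit <- tripartite(blocks, ...)
  fit$call <- match.call()
  fit
}

#' Print a tripartite fit
#'
#' @param x A `tripartite` object.
#' @param ... Ignored.
#' @export
print.tripartite <- function(x, ...) {
  rec <- x$records
  cat("Tripartite brain-gut-metabolite association fit\n")
  cat(sprintf("  %d subjects, %d cross-block tests (families: %s)\n",
              x$n_subjects, nrow(rec), x$family))
  cat(sprintf("  significant: %d at q < %g, %d at p < %g\n",
              sum(rec$sig_q), x$alpha, sum(rec$sig_p), x$alpha))
  top <- assemble_results_table(rec, x$alpha)
  top <- top[order(top$p, -abs(top$r)), , drop = FALSE]
  n_show <- min(5L, nrow(top))
  if (n_show) {
    cat("  strongest associations:\n")
    for (i in seq_len(n_show)) {
      cat(sprintf("    %-8s ~ %-14s r = %+.3f  p = %.4g  q = %.4g\n",
                  top$variable_a[i], top$variable_b[i],
                  top$r[i], top$p[i], top$q[i]))
    }
  }
  invisible(x)
}

#' Summarize a tripartite fit
#'
#' @param object A `tripartite` object.
#' @param ... Ignored.
#' @return A list of class `summary.tripartite` with the sorted association
#'   table, per-family test counts, and the effect classification.
#' @export
summary.tripartite <- function(object, ...) {
  rec <- object$records
  fam <- do.call(rbind, lapply(split(rec, rec$family), function(d) {
    data.frame(family = d$family[1], tests = nrow(d),
               sig_q = sum(d$sig_q), sig_p = sum(d$sig_p),
               stringsAsFactors = FALSE)
  }))
  rownames(fam) <- NULL
  structure(list(table = object$table, families = fam,
                 effects = object$effects, alpha = object$alpha,
                 network = object$network),
            class = "summary.tripartite")
}

#' @export
print.summary.tripartite <- function(x, ...) {
  cat("Families:\n")
  print(x$families, row.names = FALSE)
  cat(sprintf("\nNetwork (p < %g): %d nodes, %d edges\n",
              x$alpha, nrow(x$network$nodes), nrow(x$network$edges)))
  if (nrow(x$effects)) {
    cat("\nMetabolite effect classification:\n")
    print(x$effects[, c("metabolite", "target", "status", "mediators")],
          row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn tripartite Plot the metabolite first-neighbor network.
#' @export
plot.tripartite <- function(x, ...) {
  plot(x$neighborhood, ...)
}
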