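# Covariate-adjusted rank correlations across data blocks.

#' Partial Spearman correlation
#'
#' Rank correlation between `x` and `y` after removing the rank-scale linear
#' contribution of the covariates: `x`, `y` and each covariate are
#' average-rank transformed over the pairwise-complete subjects, ranked `x`
#' and ranked `y` are residualized on an intercept plus the ranked covariates
#' by least squares, and the returned coefficient is the Pearson correlation
#' of the two residual vectors. The two-sided p-value comes from
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - k`, where `k` counts the
#' linearly independent, non-constant covariates actually used (so with
#' constant covariates the result equals the plain Spearman correlation).
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional data.frame/matrix of covariates (non-numeric
#'   columns are coerced via factor codes).
#' @return A list: `r`, `p`, `n` (complete cases), `df` (= n - 2 - k), `k`,
#'   and `note` (`NA` or `"zero_variance"`, in which case `r` and `p` are
#'   `NA`).
#' @examples
#' partial_spearman(1:5, c(10, 20, 30, 40, 50), data.frame(z = rep(1, 5)))$r
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = seq_along(x))
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(x)) stop("covariates must match x in length")
  for (j in seq_along(covariates)) {
    if (!is.numeric(covariates[[j]])) {
      covariates[[j]] <- as.numeric(factor(covariates[[j]]))
    }
  }
  cc <- if (ncol(covariates)) {
    complete.cases(x, y, covariates)
  } else {
    complete.cases(x, y)
  }
  n <- sum(cc)
  k_req <- ncol(covariates)
  if (n < 4) stop("too few complete cases (", n, ")")
  rx <- rank(x[cc])
  ry <- rank(y[cc])
  if (var(rx) == 0 || var(ry) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, df = NA_integer_,
                k = NA_integer_, note = "zero_variance"))
  }
  X <- cbind(`(Intercept)` = rep(1, n))
  if (k_req > 0) {
    X <- cbind(X, vapply(covariates[cc, , drop = FALSE], rank, numeric(n)))
  }
  qx <- qr(X)
  k <- qx$rank - 1L  # constant / collinear covariates contribute nothing
  if (n < k + 4) {
    stop("too few complete cases (", n, ") for ", k, " covariate(s)")
  }
  ex <- qr.resid(qx, rx)
  ey <- qr.resid(qx, ry)
  r <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
  r <- clip(r, -1, 1)
  df <- n - 2L - k
  if (df < 1) stop("not enough degrees of freedom")
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(r) * sqrt(df / (1 - r^2)), df)
  list(r = r, p = p, n = n, df = as.integer(df), k = as.integer(k),
       note = NA_character_)
}

#' Benjamini-Hochberg q-values for one family of tests
#'
#' Step-up false-discovery-rate adjustment: with sorted p-values,
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1 and mapped back to the
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (one family).
#' @return Vector of q-values, same order as `p`.
#' @examples
#' bh_fdr(c(0.005, 0.03, 0.5))  # 0.015, 0.045, 0.5
#' @export
bh_fdr <- function(p) {
  if (!length(p)) stop("p must be a non-empty vector of p-values")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

block_defs <- function() {
  list(metabolite = c("Indole", "Skatole", "IAA"),
       clinical = c("BMI", "YFAS", "ANX"))
}

new_blocks <- function(subjects, brain, brain_meta) {
  defs <- block_defs()
  clinical <- data.frame(BMI = subjects$BMI, YFAS = subjects$YFAS,
                         ANX = subjects$HAD_anxiety)
  metab <- subjects[, defs$metabolite]
  covariates <- data.frame(age = subjects$age,
                           sex = as.numeric(subjects$sex == "F"))
  structure(list(subject_id = subjects$subject_id,
                 metabolite = metab, clinical = clinical,
                 brain = brain, brain_meta = brain_meta,
                 covariates = covariates),
            class = "bgm_blocks")
}

#' Assemble the three analysis blocks of a cohort
#'
#' Builds the metabolite block (indole, skatole, indoleacetic acid), the
#' clinical block (BMI, YFAS, HAD anxiety as `ANX`) and the brain block (one
#' column per ROI metric and modality, `NA` where a subject lacks the
#' modality), with age and sex (0 = M, 1 = F) carried as covariates.
#'
#' @param subjects Subject table from [generate_subjects()].
#' @param metrics Long node-metric table from [metrics_table()].
#' @return An object of class `bgm_blocks`.
#' @export
make_blocks <- function(subjects, metrics) {
  ids <- subjects$subject_id
  key <- unique(metrics[, c("variable", "modality")])
  key$column <- paste0(key$variable, ".",
                       ifelse(key$modality == "functional", "func", "anat"))
  brain <- as.data.frame(
    lapply(seq_len(nrow(key)), function(j) {
      sel <- metrics$variable == key$variable[j] &
        metrics$modality == key$modality[j]
      metrics$value[sel][match(ids, metrics$subject_id[sel])]
    }), col.names = key$column, check.names = FALSE)
  meta <- data.frame(column = key$column, variable = key$variable,
                     modality = key$modality, stringsAsFactors = FALSE)
  new_blocks(subjects, brain, meta)
}

#' @export
print.bgm_blocks <- function(x, ...) {
  cat(sprintf("Analysis blocks: %d subjects\n", length(x$subject_id)))
  cat(sprintf("  metabolite: %s\n", paste(names(x$metabolite), collapse = ", ")))
  cat(sprintf("  clinical:   %s\n", paste(names(x$clinical), collapse = ", ")))
  cat(sprintf("  brain:      %d variables (%d functional, %d anatomical)\n",
              nrow(x$brain_meta),
              sum(x$brain_meta$modality == "functional"),
              sum(x$brain_meta$modality == "anatomical")))
  invisible(x)
}

family_id <- function(block_a, block_b, modality,
                      family_key, variable_a) {
  switch(family_key,
         pooled = rep("all", length(block_a)),
         block_pair = paste(block_a, block_b, sep = "~"),
         block_pair_modality = ifelse(
           is.na(modality),
           paste(block_a, block_b, sep = "~"),
           paste0(block_a, "~", block_b, ":", modality)),
         source_variable = paste(variable_a, block_b, sep = "~"),
         stop("unknown family_key: ", family_key))
}

#' Cross-block association scan
#'
#' Runs [partial_spearman()] (controlling for age and sex) for every
#' cross-block variable pair — metabolites x brain metrics, clinical x brain
#' metrics, metabolites x clinical; within-block pairs are never tested.
#' Sample sizes are pairwise-complete, so YFAS pairs use only YFAS
#' completers and brain variables from excluded scans use the reduced
#' subject set. Benjamini-Hochberg q-values are attached within families.
#'
#' Both `df_test = n - 2 - k` (the degrees of freedom of the partial
#' correlation t-test) and `df_printed = n - 1` (a common reporting
#' convention for such tables) are emitted.
#'
#' @param blocks A `bgm_blocks` object.
#' @param family_key How tests are grouped for FDR correction:
#'   `"block_pair_modality"` (default; e.g. metabolite-functional is one
#'   family), `"block_pair"`, `"pooled"`, or `"source_variable"`.
#' @param alpha Significance level used for the `sig_q`/`sig_p` flags.
#' @return A data.frame of association records: `family`, `block_a`,
#'   `block_b`, `variable_a`, `variable_b`, `modality`, `r`, `p`, `q`, `n`,
#'   `df_test`, `df_printed`, `sig_q`, `sig_p`. Pairs with degenerate
#'   (zero-variance) ranks are dropped with a message.
#' @export
block_correlations <- function(blocks,
                               family_key = c("block_pair_modality",
                                              "block_pair", "pooled",
                                              "source_variable"),
                               alpha = 0.05) {
  stopifnot(inherits(blocks, "bgm_blocks"))
  family_key <- match.arg(family_key)
  cov <- blocks$covariates
  mods <- blocks$brain_meta$modality[match(names(blocks$brain),
                                           blocks$brain_meta$column)]
  vars <- blocks$brain_meta$variable[match(names(blocks$brain),
                                           blocks$brain_meta$column)]

  pairs <- rbind(
    expand.grid(a = names(blocks$metabolite), b = names(blocks$brain),
                ba = "metabolite", bb = "brain", stringsAsFactors = FALSE),
    expand.grid(a = names(blocks$clinical), b = names(blocks$brain),
                ba = "clinical", bb = "brain", stringsAsFactors = FALSE),
    expand.grid(a = names(blocks$metabolite), b = names(blocks$clinical),
                ba = "metabolite", bb = "clinical", stringsAsFactors = FALSE)
  )

  get_col <- function(block, col) blocks[[block]][[col]]
  res <- vector("list", nrow(pairs))
  dropped <- character(0)
  for (i in seq_len(nrow(pairs))) {
    x <- get_col(pairs$ba[i], pairs$a[i])
    y <- get_col(pairs$bb[i], pairs$b[i])
    ps <- tryCatch(partial_spearman(x, y, cov),
                   error = function(e) list(r = NA_real_,
                                            note = conditionMessage(e)))
    is_brain <- pairs$bb[i] == "brain"
    vb <- if (is_brain) vars[match(pairs$b[i], names(blocks$brain))] else pairs$b[i]
    mo <- if (is_brain) mods[match(pairs$b[i], names(blocks$brain))] else NA_character_
    if (is.na(ps$r)) {
      dropped <- c(dropped, paste0(pairs$a[i], "~", vb, " (", ps$note, ")"))
      next
    }
    res[[i]] <- data.frame(
      block_a = pairs$ba[i], block_b = pairs$bb[i],
      variable_a = pairs$a[i], variable_b = vb, modality = mo,
      r = ps$r, p = ps$p, n = ps$n,
      df_test = ps$df, df_printed = ps$n - 1L,
      stringsAsFactors = FALSE
    )
  }
  if (length(dropped)) {
    message("dropped ", length(dropped), " untestable pair(s): ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  out <- do.call(rbind, res)
  if (is.null(out) || !nrow(out)) stop("no testable cross-block pairs")
  out$family <- family_id(out$block_a, out$block_b, out$modality,
                          family_key, out$variable_a)
  out$q <- NA_real_
  for (f in unique(out$family)) {
    sel <- out$family == f
    out$q[sel] <- bh_fdr(out$p[sel])
  }
  out$sig_q <- out$q < alpha
  out$sig_p <- out$p < alpha
  out <- out[, c("family", "block_a", "block_b", "variable_a", "variable_b",
                 "modality", "r", "p", "q", "n", "df_test", "df_printed",
                 "sig_q", "sig_p")]
  rownames(out) <- NULL
  out
}

#' Format association records for reporting
#'
#' Sorts records within family by q, then p, then |r| descending (the
#' documented tie-break), keeping the significance flags.
#'
#' @param records Association records with q-values attached.
#' @param alpha Significance level for the flags.
#' @return The sorted data.frame (header-only if `records` is empty).
#' @export
assemble_results_table <- function(records, alpha = 0.05) {
  if (is.null(records) || !nrow(records)) {
    return(records[0, , drop = FALSE])
  }
  records$sig_q <- records$q < alpha
  records$sig_p <- records$p < alpha
  ord <- order(records$family, records$q, records$p, -abs(records$r))
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
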