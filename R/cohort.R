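# Synthetic cohort generator.
#
# A single standard-normal latent factor L per subject drives every planted
# cross-block association: a variable with loading rho is generated as
#   z_v = rho * L + sqrt(1 - rho^2) * eps,   eps ~ N(0, 1)
# and then mapped to its marginal scale (affine for BMI, exponentiation for
# metabolites, moment-calibrated rounding/truncation for questionnaire
# scores). Two variables with loadings rho_a, rho_b then have latent-scale
# correlation rho_a * rho_b, so a planted pair (a, b, rho) is realized with
# loadings sqrt(|rho|) on each side.

#' Specify a synthetic cohort
#'
#' Defaults reproduce the study conditions of the reference cohort: 63
#' right-handed healthy adults (29 male / 34 female), ages 18-60
#' (mean 29.42, SD 10.76), BMI mean 25.82 SD 4.93, Yale Food Addiction Scale
#' (YFAS, 0-7) mean 1.24 SD 1.25 completed by 42 of 63 subjects, HAD anxiety
#' (0-21) mean 4.25 SD 3.41, three positively skewed (log-normal) fecal
#' indole metabolites, a 165-region parcellation, 243 time points per
#' resting-state series (8m6s at TR = 2 s), and one subject with an excluded
#' anatomical (DTI) scan.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param n_male Number of male subjects; the rest are female.
#' @param seed Integer seed; every stage derives child seeds from it.
#' @param age_range,age_mean,age_sd Truncated-normal age model (years).
#' @param bmi_mean,bmi_sd BMI marginal (kg/m^2).
#' @param yfas_mean,yfas_sd,yfas_completion YFAS marginal (integer 0-7) and
#'   the number of subjects with a non-missing score; missingness is assigned
#'   to the last `n_subjects - yfas_completion` subject ids so that
#'   pairwise-complete sample sizes are reproducible.
#' @param anx_mean,anx_sd HAD anxiety marginal (integer 0-21).
#' @param metabolite_meanlog,metabolite_sdlog Named log-scale parameters of
#'   the three metabolite marginals (arbitrary abundance units).
#' @param loadings Named numeric vector of per-variable latent loadings
#'   rho_v in (-1, 1). Names may be subject variables (`BMI`, `YFAS`, `ANX`,
#'   `Indole`, `Skatole`, `IAA`) or brain-metric block columns such as
#'   `S_R_NAcc.func` (used by [simulate_blocks()]).
#' @param effects List of planted pairs, each `list(a=, b=, rho=)` with
#'   `|rho| < 1`; translated into loadings `sqrt(|rho|)` (sign carried on
#'   `b`) so the pair's latent correlation equals `rho`.
#' @param n_regions,t_points Parcellation size and time points per series.
#' @param baseline_cor_range Range of the (fixed, cohort-level) baseline
#'   inter-regional correlations used for time-series generation.
#' @param subject_cor_sd SD of the per-subject, per-pair perturbation of the
#'   baseline correlations (inter-individual connectome variability); each
#'   subject's perturbed matrix is repaired to the nearest positive
#'   semi-definite correlation matrix.
#' @param fiber_subject_sd SD (log scale) of the per-subject multiplicative
#'   jitter on the fiber-count intensities.
#' @param fc_shifts List of planted functional shifts, each
#'   `list(pair = c(label_a, label_b), beta =)`: the pair's correlation for
#'   subject i becomes `clip(baseline + beta * L_i, -0.99, 0.99)`.
#' @param fiber_meanlog,fiber_sdlog Log-normal model of the per-pair Poisson
#'   fiber-count intensities (fixed at the cohort level).
#' @param fiber_lambda Optional explicit intensity: a scalar or a full
#'   symmetric matrix, overriding the log-normal model.
#' @param fiber_effects List of planted anatomical effects, each
#'   `list(pair = c(label_a, label_b), gamma =)`: the pair's intensity is
#'   multiplied by `exp(gamma * L_i)`.
#' @param anat_exclude Number of subjects (taken from the end) without an
#'   anatomical scan, mirroring quality-control exclusion.
#' @param volume_seed Seed for the synthetic region volumes.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_subjects()], [simulate_cohort()], [simulate_blocks()]
#' @export
cohort_spec <- function(n_subjects = 63, n_male = 29, seed = 1,
                        age_range = c(18, 60), age_mean = 29.42, age_sd = 10.76,
                        bmi_mean = 25.82, bmi_sd = 4.93,
                        yfas_mean = 1.24, yfas_sd = 1.25, yfas_completion = 42,
                        anx_mean = 4.25, anx_sd = 3.41,
                        metabolite_meanlog = c(Indole = log(100),
                                               Skatole = log(10),
                                               IAA = log(50)),
                        metabolite_sdlog = c(Indole = 1, Skatole = 1, IAA = 1),
                        loadings = numeric(0),
                        effects = list(),
                        n_regions = 165, t_points = 243,
                        baseline_cor_range = c(0.15, 0.60),
                        subject_cor_sd = 0.1,
                        fc_shifts = list(),
                        fiber_meanlog = log(30), fiber_sdlog = 1,
                        fiber_subject_sd = 0.5,
                        fiber_lambda = NULL,
                        fiber_effects = list(),
                        anat_exclude = 1,
                        volume_seed = 1234) {
  if (n_subjects < 4) stop("n_subjects must be at least 4")
  if (n_male < 0 || n_male > n_subjects) stop("n_male out of range")
  yfas_completion <- min(yfas_completion, n_subjects)
  if (yfas_completion <= 0) stop("yfas_completion must be positive")
  if (t_points < 8) stop("t_points must be at least 8")
  for (s in c(age_sd, bmi_sd, yfas_sd, anx_sd, metabolite_sdlog)) {
    if (s <= 0) stop("marginal standard deviations must be positive")
  }
  if (!is.null(fiber_lambda) && any(fiber_lambda < 0)) {
    stop("fiber_lambda must be nonnegative")
  }
  if (anat_exclude < 0 || anat_exclude >= n_subjects) {
    stop("anat_exclude must be in [0, n_subjects)")
  }

  loadings <- resolve_loadings(loadings, effects)
  if (any(abs(loadings) >= 1)) {
    stop("latent loadings (and planted |rho|) must be strictly less than 1")
  }

  spec <- list(
    n_subjects = as.integer(n_subjects), n_male = as.integer(n_male),
    seed = as.integer(seed),
    age_range = age_range, age_mean = age_mean, age_sd = age_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    yfas_mean = yfas_mean, yfas_sd = yfas_sd,
    yfas_completion = as.integer(yfas_completion),
    anx_mean = anx_mean, anx_sd = anx_sd,
    metabolite_meanlog = metabolite_meanlog,
    metabolite_sdlog = metabolite_sdlog,
    loadings = loadings,
    n_regions = as.integer(n_regions), t_points = as.integer(t_points),
    baseline_cor_range = baseline_cor_range,
    subject_cor_sd = subject_cor_sd,
    fc_shifts = fc_shifts,
    fiber_meanlog = fiber_meanlog, fiber_sdlog = fiber_sdlog,
    fiber_subject_sd = fiber_subject_sd,
    fiber_lambda = fiber_lambda,
    fiber_effects = fiber_effects,
    anat_exclude = as.integer(anat_exclude),
    volume_seed = as.integer(volume_seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

# Merge per-pair planted effects into per-variable loadings.
resolve_loadings <- function(loadings, effects) {
  loadings <- as.numeric(loadings) |> stats::setNames(names(loadings))
  if (length(loadings) && is.null(names(loadings))) {
    stop("loadings must be a named vector")
  }
  for (ef in effects) {
    if (!all(c("a", "b", "rho") %in% names(ef))) {
      stop("each planted effect needs fields a, b, rho")
    }
    if (abs(ef$rho) >= 1) stop("planted correlation magnitudes must be in (-1, 1)")
    la <- sqrt(abs(ef$rho))
    lb <- sign(ef$rho) * sqrt(abs(ef$rho))
    for (vl in list(c(ef$a, la), c(ef$b, lb))) {
      v <- vl[1]; l <- as.numeric(vl[2])
      if (!is.null(names(loadings)) && v %in% names(loadings)) {
        if (abs(loadings[[v]] - l) > 1e-10) {
          stop("conflicting loadings implied for variable '", v,
               "'; specify `loadings` explicitly instead of `effects`")
        }
      } else {
        loadings[v] <- l
      }
    }
  }
  loadings
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  subjects: %d (%d M / %d F), seed %d\n",
              x$n_subjects, x$n_male, x$n_subjects - x$n_male, x$seed))
  cat(sprintf("  regions: %d, time points: %d\n", x$n_regions, x$t_points))
  cat(sprintf("  YFAS completion: %d/%d; anatomical scans excluded: %d\n",
              x$yfas_completion, x$n_subjects, x$anat_exclude))
  if (length(x$loadings)) {
    cat("  latent loadings:",
        paste(sprintf("%s=%.3f", names(x$loadings), x$loadings),
              collapse = ", "), "\n")
  } else {
    cat("  no planted effects (global null)\n")
  }
  invisible(x)
}

# Exact moments of round(N(m, s)) clipped to [lo, hi].
discretized_moments <- function(m, s, lo, hi) {
  ks <- lo:hi
  up <- pnorm((ks + 0.5 - m) / s)
  up[length(up)] <- 1
  p <- diff(c(0, up))
  mu <- sum(ks * p)
  c(mean = mu, sd = sqrt(max(sum(ks^2 * p) - mu^2, 0)))
}

# Latent (mean, sd) such that the rounded, clipped score matches the target
# mean/SD. Deterministic moment matching; no randomness involved.
calibrate_discrete <- function(target_mean, target_sd, lo, hi) {
  obj <- function(par) {
    mm <- discretized_moments(par[1], exp(par[2]), lo, hi)
    (mm[1] - target_mean)^2 + (mm[2] - target_sd)^2
  }
  o <- optim(c(target_mean, log(target_sd)), obj,
             control = list(reltol = 1e-12, maxit = 2000))
  c(mean = o$par[1], sd = exp(o$par[2]))
}

#' Generate the subject table
#'
#' Draws demographics, clinical scores and metabolite levels for one cohort.
#' Deterministic given the spec's seed. The hidden latent factor is emitted
#' as column `latent` for test introspection only; it is not part of any
#' analysis block.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with one row per subject: `subject_id`, `age`, `sex`
#'   ("M"/"F"), `BMI`, `YFAS` (0-7, `NA` for non-completers), `HAD_anxiety`
#'   (0-21), `Indole`, `Skatole`, `IAA` (positive abundances), `latent`.
#' @examples
#' subj <- generate_subjects(cohort_spec(seed = 1))
#' sum(is.na(subj$YFAS))  # 21 of 63
#' @export
generate_subjects <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  with_seed(child_seed(spec$seed, 1L), {
    L <- rnorm(n)
    load_of <- function(v) {
      if (v %in% names(spec$loadings)) spec$loadings[[v]] else 0
    }
    latent_of <- function(v) {
      rho <- load_of(v)
      rho * L + sqrt(1 - rho^2) * rnorm(n)
    }

    lo <- pnorm((spec$age_range[1] - spec$age_mean) / spec$age_sd)
    hi <- pnorm((spec$age_range[2] - spec$age_mean) / spec$age_sd)
    age <- spec$age_mean + spec$age_sd * qnorm(runif(n, lo, hi))

    sex <- rep(c("M", "F"), c(spec$n_male, n - spec$n_male))
    bmi <- spec$bmi_mean + spec$bmi_sd * latent_of("BMI")

    yf_par <- calibrate_discrete(spec$yfas_mean, spec$yfas_sd, 0, 7)
    yfas <- clip(round(yf_par[1] + yf_par[2] * latent_of("YFAS")), 0, 7)
    ax_par <- calibrate_discrete(spec$anx_mean, spec$anx_sd, 0, 21)
    anx <- clip(round(ax_par[1] + ax_par[2] * latent_of("ANX")), 0, 21)

    mets <- lapply(names(spec$metabolite_meanlog), function(m) {
      exp(spec$metabolite_meanlog[[m]] + spec$metabolite_sdlog[[m]] * latent_of(m))
    })
    names(mets) <- names(spec$metabolite_meanlog)

    if (spec$yfas_completion < n) {
      yfas[(spec$yfas_completion + 1):n] <- NA
    }

    out <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      age = age, sex = sex, BMI = bmi,
      YFAS = as.numeric(yfas), HAD_anxiety = as.numeric(anx),
      stringsAsFactors = FALSE
    )
    for (m in names(mets)) out[[m]] <- mets[[m]]
    out$latent <- L
    out
  })
}

# Fixed cohort-level baseline inter-regional correlation matrix.
baseline_correlation <- function(spec, n_regions) {
  with_seed(child_seed(spec$seed, 2L), {
    M <- diag(n_regions)
    ut <- upper.tri(M)
    M[ut] <- runif(sum(ut), spec$baseline_cor_range[1], spec$baseline_cor_range[2])
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    psd_repair(M)
  })
}

resolve_pairs <- function(pairs, labels, what) {
  lapply(pairs, function(p) {
    idx <- match(p$pair, labels)
    if (anyNA(idx)) {
      stop(what, " names a region absent from the parcellation: ",
           paste(p$pair[is.na(idx)], collapse = ", "))
    }
    list(i = min(idx), j = max(idx), coef = p[[setdiff(names(p), "pair")[1]]])
  })
}

#' Generate per-subject region time series
#'
#' Each subject's series is drawn from a zero-mean multivariate normal whose
#' correlation matrix equals the cohort baseline with any planted shifts
#' `beta * L_i` applied to the designated region pairs (clipped into
#' (-0.99, 0.99)); shifted matrices are repaired to the nearest positive
#' semi-definite correlation matrix. Stands in for preprocessed, region-
#' averaged BOLD signals.
#'
#' @param subjects Subject table from [generate_subjects()].
#' @param regions Region table from [build_parcellation()].
#' @param spec The [cohort_spec()].
#' @return Named list (by subject id) of `t_points x n_regions` matrices with
#'   region labels as column names.
#' @export
generate_timeseries <- function(subjects, regions, spec) {
  n_r <- nrow(regions)
  if (spec$t_points <= n_r) {
    warning("t_points <= n_regions: sample correlation matrices are rank deficient")
  }
  base <- baseline_correlation(spec, n_r)
  shifts <- resolve_pairs(spec$fc_shifts, regions$label, "fc_shifts")
  ch_base <- chol(base + diag(1e-10, n_r))
  jit_sd <- spec$subject_cor_sd
  ut <- upper.tri(base)
  out <- vector("list", nrow(subjects))
  names(out) <- subjects$subject_id
  for (i in seq_len(nrow(subjects))) {
    out[[i]] <- with_seed(child_seed(spec$seed, 3L, i), {
      if (jit_sd > 0 || length(shifts)) {
        R <- base
        if (jit_sd > 0) {
          J <- matrix(0, n_r, n_r)
          J[ut] <- rnorm(sum(ut), 0, jit_sd)
          J[lower.tri(J)] <- t(J)[lower.tri(J)]
          R <- clip(R + J, -0.99, 0.99)
          diag(R) <- 1
        }
        for (sh in shifts) {
          r <- clip(base[sh$i, sh$j] + sh$coef * subjects$latent[i], -0.99, 0.99)
          R[sh$i, sh$j] <- R[sh$j, sh$i] <- r
        }
        R <- psd_repair(R)
        ch <- chol(R + diag(1e-10, n_r))
      } else {
        ch <- ch_base
      }
      ts <- matrix(rnorm(spec$t_points * n_r), spec$t_points) %*% ch
      colnames(ts) <- regions$label
      ts
    })
  }
  out
}

#' Generate per-subject fiber-count matrices
#'
#' Counts for each unordered region pair are independent Poisson draws with
#' intensity `lambda_ij * exp(gamma * L_i)` on planted pairs (lambda_ij
#' fixed at the cohort level, log-normal unless `fiber_lambda` is given).
#' Matrices are symmetric with zero diagonal. The last `anat_exclude`
#' subjects get no matrix, mirroring a quality-control exclusion. Stands in
#' for tractography output.
#'
#' @inheritParams generate_timeseries
#' @return A list with `counts` (named list of matrices for non-excluded
#'   subjects) and `volumes` (per-region volumes from `regions`).
#' @export
generate_fiber_counts <- function(subjects, regions, spec) {
  n_r <- nrow(regions)
  lam <- spec$fiber_lambda
  if (is.null(lam)) {
    lam <- with_seed(child_seed(spec$seed, 4L), {
      M <- matrix(0, n_r, n_r)
      ut <- upper.tri(M)
      M[ut] <- exp(rnorm(sum(ut), spec$fiber_meanlog, spec$fiber_sdlog))
      M[lower.tri(M)] <- t(M)[lower.tri(M)]
      M
    })
  } else if (length(lam) == 1) {
    lam <- matrix(lam, n_r, n_r)
  }
  if (any(lam < 0)) stop("fiber intensities must be nonnegative")
  diag(lam) <- 0
  plants <- resolve_pairs(spec$fiber_effects, regions$label, "fiber_effects")

  n_keep <- nrow(subjects) - spec$anat_exclude
  out <- vector("list", n_keep)
  names(out) <- subjects$subject_id[seq_len(n_keep)]
  ut <- upper.tri(lam)
  for (i in seq_len(n_keep)) {
    out[[i]] <- with_seed(child_seed(spec$seed, 5L, i), {
      lam_i <- lam
      if (spec$fiber_subject_sd > 0) {
        jit <- matrix(1, n_r, n_r)
        jit[ut] <- exp(rnorm(sum(ut), 0, spec$fiber_subject_sd))
        lam_i <- lam_i * jit  # only the upper triangle is sampled below
      }
      for (pl in plants) {
        lam_i[pl$i, pl$j] <- lam_i[pl$j, pl$i] <-
          lam_i[pl$i, pl$j] * exp(pl$coef * subjects$latent[i])
      }
      counts <- matrix(0, n_r, n_r)
      counts[ut] <- rpois(sum(ut), lam_i[ut])
      counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
      dimnames(counts) <- list(regions$label, regions$label)
      counts
    })
  }
  list(counts = out, volumes = regions$volume)
}

#' Simulate a full cohort
#'
#' Runs [generate_subjects()], [generate_timeseries()] and
#' [generate_fiber_counts()] over one parcellation and bundles the result.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `bgm_cohort`: list with `spec`, `regions`,
#'   `subjects`, `timeseries`, `fibers`.
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_subjects = 8, n_male = 4,
#'                                    n_regions = 20, t_points = 60,
#'                                    yfas_completion = 6, seed = 7))
#' coh
#' @export
simulate_cohort <- function(spec) {
  regions <- build_parcellation(spec$n_regions, spec$volume_seed)
  subjects <- generate_subjects(spec)
  structure(
    list(spec = spec, regions = regions, subjects = subjects,
         timeseries = generate_timeseries(subjects, regions, spec),
         fibers = generate_fiber_counts(subjects, regions, spec)),
    class = "bgm_cohort"
  )
}

#' @export
print.bgm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d regions (%d ROIs)\n",
              nrow(x$subjects), nrow(x$regions), sum(x$regions$is_roi)))
  cat(sprintf("  functional series: %d x %d per subject; anatomical scans: %d\n",
              x$spec$t_points, nrow(x$regions), length(x$fibers$counts)))
  invisible(x)
}

#' Simulate analysis blocks directly from the latent-factor model
#'
#' Generates the three analysis blocks (metabolites, clinical scores,
#' brain-metric variables) without the imaging stage: every brain-metric
#' variable (12 ROIs x strength/betweenness x functional/anatomical) is drawn
#' from the same latent factor with its configured loading and a log-normal
#' marginal. Use this for statistical calibration experiments (power, null
#' error control of the association stage); use [simulate_cohort()] +
#' [tripartite()] when the connectome stages themselves are under study.
#' Plants named like `S_R_NAcc.func` / `B_L_Amg.anat` in `spec$loadings`
#' (or via `effects`) are realized here.
#'
#' @param spec A [cohort_spec()].
#' @return A `bgm_blocks` object (see [make_blocks()]).
#' @examples
#' sp <- cohort_spec(seed = 3,
#'                   effects = list(list(a = "Indole", b = "S_R_NAcc.func",
#'                                       rho = 0.6)))
#' blk <- simulate_blocks(sp)
#' @export
simulate_blocks <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- generate_subjects(spec)
  regions <- build_parcellation(spec$n_regions, spec$volume_seed)
  rois <- roi_labels(regions)
  grid <- expand.grid(metric = c("S", "B"), roi = rois,
                      modality = c("functional", "anatomical"),
                      stringsAsFactors = FALSE)
  cols <- paste0(grid$metric, "_", grid$roi, ".",
                 ifelse(grid$modality == "functional", "func", "anat"))
  n <- nrow(subjects)
  L <- subjects$latent
  brain <- with_seed(child_seed(spec$seed, 6L), {
    vals <- lapply(seq_along(cols), function(j) {
      rho <- if (cols[j] %in% names(spec$loadings)) spec$loadings[[cols[j]]] else 0
      exp(rho * L + sqrt(1 - rho^2) * rnorm(n))
    })
    names(vals) <- cols
    as.data.frame(vals, check.names = FALSE)
  })
  if (spec$anat_exclude > 0) {
    excl <- (n - spec$anat_exclude + 1):n
    brain[excl, grid$modality == "anatomical"] <- NA
  }
  meta <- data.frame(column = cols,
                     variable = paste0(grid$metric, "_", grid$roi),
                     modality = grid$modality, stringsAsFactors = FALSE)
  new_blocks(subjects, brain, meta)
}
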