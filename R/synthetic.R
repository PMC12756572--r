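# Synthetic cohort generator.
#
# Emulates the statistical structure of a 382-child critical-illness cohort
# with two latent whole-blood endotypes: a cell-mixture expression model with
# endotype-specific Dirichlet fractions, planted endotype marker genes,
# gene-wise variances from a scaled inverse-chi-square hierarchy, age-group
# confounding, and clinical outcomes (ventilation days, 30-day mortality)
# calibrated so the marginal VFD-30 deficit in endotype 1 hits a target.

# Endotype-conditional categorical tables. Proportions follow the published
# cohort's clinical characteristics table (counts over 122 endotype-1 and
# 260 endotype-2 children).
AGE_PROBS <- list(
  e1 = c(65, 35, 3, 8, 7, 4) / 122,
  e2 = c(13, 39, 50, 67, 71, 20) / 260
)
REASON_PROBS <- list(
  e1 = c(41, 27, 7, 32, 1, 1, 13) / 122,
  e2 = c(121, 50, 48, 8, 18, 5, 10) / 260
)
INFECTION_PROBS <- list(
  e1 = c(60, 17, 26, 19) / 122,
  e2 = c(83, 46, 65, 66) / 260
)
# any-comorbidity probability by endotype (62/122, 131/260); the "any" mass
# is spread over the non-none categories.
COMORBIDITY_ANY <- c(e1 = 62 / 122, e2 = 131 / 260)

# Cell types of the generated signature. Endotype 1 up-weights naive and
# resting-memory CD4-like types and down-weights the neutrophil-like type
# (the direction the deconvolution stage must recover); endotype 2 is
# neutrophil-dominated.
CELL_TYPES <- c("neutrophils", "cd4_naive", "cd4_memory_resting",
                "cd4_activated", "monocytes", "nk_cells")
DIRICHLET_ALPHA <- list(
  e1 = c(neutrophils = 6, cd4_naive = 5, cd4_memory_resting = 4,
         cd4_activated = 1.5, monocytes = 3, nk_cells = 2),
  e2 = c(neutrophils = 14, cd4_naive = 2, cd4_memory_resting = 2,
         cd4_activated = 3, monocytes = 3, nk_cells = 2)
)

# PIM2 logit-normal locations by endotype (medians 0.080 / 0.052) and common
# scale matching the published interquartile ranges.
PIM2_MEANLOGIT <- c(e1 = -2.44, e2 = -2.90)
PIM2_SDLOGIT <- 1.0
# Ventilation-day lognormal for endotype 2 (median 4 days, IQR about 2-7).
VENT_MEANLOG <- log(4)
VENT_SDLOG <- 0.9
# Slope of 30-day death on logit(PIM2); intercept is calibrated at run time
# to the target marginal mortality.
DEATH_SLOPE <- 0.8

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the study conditions: 382 children, endotype-1
#' prevalence 0.319, a 3.7-day VFD-30 deficit in endotype 1, 4.2% baseline
#' 30-day mortality, and gene-wise variances from a scaled
#' inverse-chi-square prior with d0 = 4 and s0^2 = 0.05.
#'
#' @param n_samples Number of children.
#' @param n_genes Number of genes on the array after collapsing.
#' @param n_cell_types Number of leukocyte types in the signature (max 6).
#' @param endotype1_prevalence Probability a child belongs to endotype 1.
#' @param n_marker_genes Number of planted endotype marker genes.
#' @param marker_effect_log2 Length-2 range of absolute log2 marker effects.
#' @param d0 Prior degrees of freedom of the gene-variance hierarchy.
#' @param s0_sq Prior variance of the gene-variance hierarchy.
#' @param vfd_effect_days Target marginal difference E[VFD-30 | endotype 1] -
#'   E[VFD-30 | endotype 2], in days (non-positive, > -30).
#' @param base_mortality Target marginal 30-day mortality.
#' @param seed Integer seed; every stage stream is derived from it.
#' @param dirichlet_alpha Optional list with elements `e1` and `e2` giving
#'   cell-fraction Dirichlet concentrations per endotype, overriding the
#'   built-in endotype-specific defaults (pass two equal vectors for a null
#'   cohort with no mixture difference between endotypes).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 382, n_genes = 2000, n_cell_types = 6,
                        endotype1_prevalence = 0.319, n_marker_genes = 150,
                        marker_effect_log2 = c(1.5, 3.0), d0 = 4,
                        s0_sq = 0.05, vfd_effect_days = -3.7,
                        base_mortality = 0.042, seed = 1L,
                        dirichlet_alpha = NULL) {
  spec <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
               n_cell_types = as.integer(n_cell_types),
               endotype1_prevalence = endotype1_prevalence,
               n_marker_genes = as.integer(n_marker_genes),
               marker_effect_log2 = marker_effect_log2, d0 = d0, s0_sq = s0_sq,
               vfd_effect_days = vfd_effect_days,
               base_mortality = base_mortality, seed = as.integer(seed),
               dirichlet_alpha = dirichlet_alpha)
  if (spec$endotype1_prevalence <= 0 || spec$endotype1_prevalence >= 1)
    stop("endotype1_prevalence must lie in (0, 1)")
  if (any(c(spec$n_samples, spec$n_genes, spec$n_cell_types,
            spec$n_marker_genes) <= 0))
    stop("all counts must be positive")
  if (spec$n_marker_genes > spec$n_genes)
    stop("n_marker_genes cannot exceed n_genes")
  if (spec$n_cell_types > length(CELL_TYPES))
    stop("at most ", length(CELL_TYPES), " cell types are available")
  if (spec$vfd_effect_days > 0 || spec$vfd_effect_days <= -30)
    stop("vfd_effect_days must lie in (-30, 0]")
  if (spec$base_mortality <= 0 || spec$base_mortality >= 1)
    stop("base_mortality must lie in (0, 1)")
  class(spec) <- "cohort_spec"
  spec
}

# Named per-stage generator streams derived from the single global seed, so
# individual stages can be re-simulated in isolation.
stage_seeds <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister")
  s <- sample.int(.Machine$integer.max - 1L, 8L)
  names(s) <- c("labels", "clinical", "signature", "variances", "markers",
                "expression", "outcomes", "genesets")
  s
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# Intercept of the death model solved so the marginal mortality over the
# endotype-mixture PIM2 distribution equals the target.
calibrate_mortality_intercept <- function(spec, n_mc = 2e5) {
  set.seed(stage_seeds(spec$seed)[["outcomes"]] %% 1000003L + 7L)
  z <- stats::rbinom(n_mc, 1, spec$endotype1_prevalence)
  lp <- stats::rnorm(n_mc,
                     ifelse(z == 1, PIM2_MEANLOGIT["e1"], PIM2_MEANLOGIT["e2"]),
                     PIM2_SDLOGIT)
  f <- function(a) mean(stats::plogis(a + DEATH_SLOPE * lp)) - spec$base_mortality
  stats::uniroot(f, c(-20, 5), tol = 1e-10)$root
}

#' Calibrate the ventilation-model location shift for a VFD-30 target
#'
#' Finds the shift added to the lognormal ventilation-day location of
#' endotype-1 children so that the marginal VFD-30 difference between
#' endotypes (deaths counted as VFD-30 = 0, ventilation capped at 30 days)
#' equals `spec$vfd_effect_days`. Solved by 1-D root finding on a
#' common-random-number Monte-Carlo estimate (1e5 draws per endotype), since
#' truncation at 30 days and death-as-zero leave no closed form.
#'
#' @param spec A [cohort_spec()].
#' @param n_mc Monte-Carlo draws per endotype.
#' @return The location shift (log-days) for endotype 1.
#' @export
calibrate_outcome_shift <- function(spec, n_mc = 1e5) {
  if (spec$vfd_effect_days == 0) return(0)
  a <- calibrate_mortality_intercept(spec)
  set.seed(stage_seeds(spec$seed)[["outcomes"]] %% 1000003L + 11L)
  zvent <- stats::rnorm(n_mc)
  lp1 <- stats::rnorm(n_mc, PIM2_MEANLOGIT["e1"], PIM2_SDLOGIT)
  lp2 <- stats::rnorm(n_mc, PIM2_MEANLOGIT["e2"], PIM2_SDLOGIT)
  u <- stats::runif(n_mc)
  mean_vfd <- function(meanlog, lp) {
    vent <- round(exp(meanlog + VENT_SDLOG * zvent))
    died <- u < stats::plogis(a + DEATH_SLOPE * lp)
    mean(ifelse(died | vent >= 30, 0, 30 - vent))
  }
  base2 <- mean_vfd(VENT_MEANLOG, lp2)
  g <- function(delta) mean_vfd(VENT_MEANLOG + delta, lp1) - base2 -
    spec$vfd_effect_days
  if (g(0) * g(3) > 0)
    stop("outcome-shift calibration did not bracket a root; ",
         "vfd_effect_days target infeasible under the ventilation model")
  stats::uniroot(g, c(0, 3), tol = 1e-6)$root
}

#' Simulate a synthetic critical-illness cohort with ground truth
#'
#' Expression is generated as a cell-type mixture plus endotype marker
#' effects plus gene-wise Gaussian noise:
#' `X[g,i] = sum_c S[g,c] f[i,c] + delta_g 1(z_i = 1) + eps`, with
#' `eps ~ N(0, sigma_g^2)` and `sigma_g^2 ~ s0_sq * d0 / chisq(d0)`. Cell
#' fractions are Dirichlet with endotype-specific concentrations (endotype 1:
#' naive/resting CD4 up, neutrophils down). Age group, admission reason and
#' infection status are drawn from endotype-conditional tables mirroring the
#' study cohort, making age a confounder of endotype membership. Ventilation
#' days are rounded lognormal with the endotype-1 location shifted by
#' [calibrate_outcome_shift()]; 30-day death is Bernoulli on the logit of
#' PIM2, calibrated to the target marginal mortality.
#'
#' @param spec A [cohort_spec()].
#' @return List with `expression` ([expression_matrix()]), `clinical`
#'   (`clinical_table`), `truth` (labels, cell fractions, marker ids and
#'   effects, gene variances), `signature` (genes x cell types matrix of the
#'   cell-type profiles actually mixed) and `sets` (a `gene_set_collection`
#'   with the up-marker set, the down-marker set and 20 decoy sets).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- stage_seeds(spec$seed)
  n <- spec$n_samples
  G <- spec$n_genes
  C <- spec$n_cell_types
  gene_ids <- sprintf("G%04d", seq_len(G))
  sample_ids <- sprintf("S%04d", seq_len(n))
  cells <- CELL_TYPES[seq_len(C)]

  set.seed(seeds[["labels"]])
  z <- stats::rbinom(n, 1, spec$endotype1_prevalence)

  # clinical covariates conditional on endotype
  set.seed(seeds[["clinical"]])
  pick <- function(probs, vocab) {
    idx <- ifelse(z == 1, 1L, 2L)
    vapply(idx, function(i) sample(vocab[seq_along(probs[[i]])], 1L,
                                   prob = probs[[i]]), character(1))
  }
  age_group <- pick(AGE_PROBS, CLINICAL_VOCAB$age_group)
  reason <- pick(REASON_PROBS, CLINICAL_VOCAB$admission_reason)
  infection <- pick(INFECTION_PROBS, CLINICAL_VOCAB$infection_status)
  sex <- sample(CLINICAL_VOCAB$sex, n, replace = TRUE, prob = c(0.474, 0.526))
  p_any <- ifelse(z == 1, COMORBIDITY_ANY["e1"], COMORBIDITY_ANY["e2"])
  has_com <- stats::runif(n) < p_any
  comorbidity <- ifelse(has_com,
                        sample(CLINICAL_VOCAB$comorbidity[-1], n, replace = TRUE),
                        "none")
  pim2 <- stats::plogis(stats::rnorm(
    n, ifelse(z == 1, PIM2_MEANLOGIT["e1"], PIM2_MEANLOGIT["e2"]), PIM2_SDLOGIT))
  pim2 <- pmin(pmax(pim2, 1e-4), 1 - 1e-4)

  # signature matrix: log-normal cell-specific profiles with marker blocks
  set.seed(seeds[["signature"]])
  S <- matrix(stats::rnorm(G * C, mean = 6, sd = 0.5), G, C,
              dimnames = list(gene_ids, cells))
  block <- split(seq_len(G), rep(seq_len(C), length.out = G))
  for (c_i in seq_len(C)) {
    mk <- sample(block[[c_i]], min(40L, length(block[[c_i]])))
    S[mk, c_i] <- S[mk, c_i] + stats::runif(length(mk), 2, 4)
  }

  # gene-wise variances from the scaled inverse-chi-square hierarchy
  set.seed(seeds[["variances"]])
  sigma_sq <- spec$s0_sq * spec$d0 / stats::rchisq(G, df = spec$d0)

  # planted endotype markers
  set.seed(seeds[["markers"]])
  marker_idx <- sort(sample.int(G, spec$n_marker_genes))
  lo <- spec$marker_effect_log2[1]; hi <- spec$marker_effect_log2[2]
  magnitude <- if (hi > lo) stats::runif(spec$n_marker_genes, lo, hi)
               else rep(lo, spec$n_marker_genes)
  sign_up <- rep(c(1, -1), length.out = spec$n_marker_genes)
  delta <- numeric(G)
  delta[marker_idx] <- magnitude * sign_up

  # expression
  set.seed(seeds[["expression"]])
  alpha_src <- if (is.null(spec$dirichlet_alpha)) DIRICHLET_ALPHA
               else spec$dirichlet_alpha
  alpha <- lapply(alpha_src, function(a) a[seq_len(C)])
  fractions <- matrix(NA_real_, n, C, dimnames = list(sample_ids, cells))
  fractions[z == 1, ] <- rdirichlet(sum(z == 1), alpha$e1)
  fractions[z == 0, ] <- rdirichlet(sum(z == 0), alpha$e2)
  X <- S %*% t(fractions) + outer(delta, z) +
    matrix(stats::rnorm(G * n, sd = sqrt(sigma_sq)), G, n)
  dimnames(X) <- list(gene_ids, sample_ids)

  # outcomes
  a_death <- calibrate_mortality_intercept(spec)
  shift <- if (spec$vfd_effect_days == 0) 0 else calibrate_outcome_shift(spec)
  set.seed(seeds[["outcomes"]])
  vent <- round(exp(VENT_MEANLOG + shift * z +
                      VENT_SDLOG * stats::rnorm(n)))
  vent <- pmax(as.integer(vent), 0L)
  died <- stats::runif(n) < stats::plogis(a_death + DEATH_SLOPE * stats::qlogis(pim2))

  clinical <- validate_clinical(data.frame(
    sample_id = sample_ids, sex = sex, age_group = age_group,
    admission_reason = reason, comorbidity = comorbidity,
    infection_status = infection, pim2 = pim2, ventilation_days = vent,
    died_by_day30 = died, vasoactive = stats::runif(n) < ifelse(z == 1, 0.803, 0.477),
    stringsAsFactors = FALSE))

  # gene sets: planted up/down marker sets plus 20 random decoys
  set.seed(seeds[["genesets"]])
  up_ids <- gene_ids[marker_idx][sign_up > 0]
  dn_ids <- gene_ids[marker_idx][sign_up < 0]
  sets <- c(list(ENDOTYPE1_UP = up_ids, ENDOTYPE1_DOWN = dn_ids),
            setNames(lapply(seq_len(20), function(i)
              sample(gene_ids, min(G, sample(25:60, 1)))),
              sprintf("DECOY_%02d", seq_len(20))))
  gsc <- structure(list(
    sets = sets,
    descriptions = setNames(c("planted up-markers", "planted down-markers",
                              rep("random decoy", 20)), names(sets)),
    n_duplicates_dropped = 0L), class = "gene_set_collection")

  truth <- list(endotype = 2L - z, cell_fractions = fractions,
                marker_gene_ids = gene_ids[marker_idx],
                true_effects = setNames(delta[marker_idx], gene_ids[marker_idx]),
                gene_variances = setNames(sigma_sq, gene_ids),
                vent_location_shift = shift,
                death_intercept = a_death)

  list(expression = expression_matrix(X, gene_ids, sample_ids, level = "gene"),
       clinical = clinical, truth = truth, signature = S, sets = gsc)
}
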