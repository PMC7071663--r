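#' Configuration for the synthetic-data generators
#'
#' Bundles the parameters that define the simulated study conditions:
#' eight experts judging the five default criteria around the published
#' latent weights with multiplicative log-normal noise, positively
#' skewed (log-normal) criterion values per intervention, and inpatient
#' claims concentrated on the 33 reference ICD-10 codes.
#'
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @param latent_weights positive named weight vector the experts judge
#'   around; defaults to [ncd_criteria_weights()].
#' @param n_experts number of expert matrices (default 8).
#' @param expert_noise_sd standard deviation of the log-scale judgment
#'   noise (default 0.2).
#' @param saaty_rounding round generated judgments to the nearest Saaty
#'   scale value \{1/9..1/2, 1..9\} (default FALSE).
#' @param lognormal_meanlog,lognormal_sdlog log-scale location and
#'   scale of the drawn criterion values (criteria 1, 3 and 5).
#' @param claims_n_records number of synthetic claims records.
#' @param claims_total_admissions total admissions to distribute.
#' @param claims_concentration fraction of admissions falling on the
#'   reference ICD-10 codes, in [0, 1].
#' @return a list of class \code{"synth_config"}.
#' @export
synth_config <- function(seed = 1,
                         latent_weights = ncd_criteria_weights(),
                         n_experts = 8L,
                         expert_noise_sd = 0.2,
                         saaty_rounding = FALSE,
                         lognormal_meanlog = c(people_affected = 11,
                                               attributable_burden = 6,
                                               income_inequity = 1),
                         lognormal_sdlog = c(people_affected = 1,
                                             attributable_burden = 0.8,
                                             income_inequity = 0.6),
                         claims_n_records = 2000L,
                         claims_total_admissions = 2400000L,
                         claims_concentration = 0.15) {
  stopifnot(all(latent_weights > 0), n_experts >= 1,
            all(lognormal_sdlog > 0), claims_n_records > 0,
            claims_total_admissions > 0)
  if (claims_concentration < 0 || claims_concentration > 1)
    stop("claims_concentration must lie in [0, 1]", call. = FALSE)
  out <- list(seed = as.integer(seed), latent_weights = latent_weights,
              n_experts = as.integer(n_experts),
              expert_noise_sd = expert_noise_sd,
              saaty_rounding = saaty_rounding,
              lognormal_meanlog = lognormal_meanlog,
              lognormal_sdlog = lognormal_sdlog,
              claims_n_records = as.integer(claims_n_records),
              claims_total_admissions = as.integer(claims_total_admissions),
              claims_concentration = claims_concentration)
  class(out) <- "synth_config"
  out
}

saaty_scale <- function() c(1 / (9:2), 1:9)

#' Generate synthetic expert judgment matrices
#'
#' For each expert, the upper triangle is drawn as \code{a[i,j] =
#' (w[i]/w[j]) * exp(e)} with \code{e ~ Normal(0, sd)} independently;
#' the lower triangle is set to the exact reciprocal, so every
#' generated matrix satisfies the reciprocity invariant by
#' construction. Optionally the judgments are snapped to the nearest
#' Saaty scale value before reciprocals are taken.
#'
#' @param config a [synth_config()]; \code{expert_noise_sd} must be
#'   positive (use [build_consistent_matrix()] for the noiseless case).
#' @return list of \code{n_experts} reciprocal matrices.
#' @export
gen_expert_matrices <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (config$expert_noise_sd <= 0)
    stop("expert_noise_sd must be positive; use build_consistent_matrix()",
         " for noiseless judgments", call. = FALSE)
  w <- config$latent_weights
  n <- length(w)
  restore <- .Random.seed_guard(config$seed)
  on.exit(restore())
  lapply(seq_len(config$n_experts), function(e) {
    a <- diag(n)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        v <- (w[[i]] / w[[j]]) * exp(stats::rnorm(1, 0, config$expert_noise_sd))
        if (config$saaty_rounding) {
          s <- saaty_scale()
          v <- s[which.min(abs(log(s) - log(v)))]
        }
        a[i, j] <- v
        a[j, i] <- 1 / v
      }
    }
    dimnames(a) <- list(names(w), names(w))
    a
  })
}

#' Generate synthetic inpatient claims records
#'
#' Splits the total admissions between the 33 reference ICD-10 codes
#' and random out-of-scope codes: a Binomial(total, concentration) draw
#' decides the mapped share, the mapped admissions are spread over the
#' reference codes by a Dirichlet-perturbed multinomial, and the
#' remainder goes to synthetic non-reference codes. Total admissions
#' are conserved exactly.
#'
#' @param config a [synth_config()].
#' @param map reference code map, defaults to [ncd_icd10_map()].
#' @return data frame with columns \code{icd10_code, admissions}.
#' @export
gen_claims <- function(config = synth_config(), map = ncd_icd10_map()) {
  stopifnot(inherits(config, "synth_config"))
  restore <- .Random.seed_guard(config$seed + 1L)
  on.exit(restore())
  total <- config$claims_total_admissions
  mapped_total <- stats::rbinom(1, total, config$claims_concentration)
  ref <- map$icd10_code
  ## Dirichlet(1,...,1) perturbation of the code-level multinomial
  alpha <- stats::rgamma(length(ref), shape = 1)
  p <- alpha / sum(alpha)
  mapped <- as.integer(stats::rmultinom(1, mapped_total, p))
  n_other <- max(config$claims_n_records - length(ref), 1L)
  other_codes <- sprintf("X%02d.%d",
                         sample(0:99, n_other, replace = TRUE),
                         sample(0:9, n_other, replace = TRUE))
  other_codes <- make.unique(other_codes, sep = "u")
  other_codes <- setdiff(other_codes, ref)
  unmapped_total <- total - mapped_total
  other <- if (unmapped_total > 0 && length(other_codes))
    as.integer(stats::rmultinom(1, unmapped_total,
                                rep(1, length(other_codes)))) else
    integer(length(other_codes))
  out <- data.frame(
    icd10_code = c(ref, other_codes),
    admissions = c(mapped, other),
    stringsAsFactors = FALSE)
  out[out$admissions > 0 | out$icd10_code %in% ref, , drop = FALSE]
}

#' Generate a synthetic interventions-by-criteria matrix
#'
#' Draws the "people affected", "attributable burden" and "income
#' inequity" criteria from configured log-normal distributions (positive
#' and right-skewed, as in the national survey and burden-of-disease
#' sources they stand in for); encodes cost-effectiveness from the
#' catalog tier (best buy = 3, effective = 2, no analysis = 1); and
#' computes the hospitalization criterion through the claims pathway
#' (generated claims, aggregated into disease groups, scored by the 4x4
#' model), so the cross-module dependency is exercised rather than
#' simulated away.
#'
#' @param config a [synth_config()].
#' @param subset an \code{"ncd_catalog"} of the interventions to score
#'   (typically [filter_prioritizable()] output).
#' @param tier_values numeric encoding of the cost-effectiveness tiers.
#' @return numeric matrix, rows = intervention codes, columns = the five
#'   criteria.
#' @export
gen_criteria_matrix <- function(config = synth_config(), subset,
                                tier_values = c(best_buy = 3,
                                                effective_gt_100 = 2,
                                                no_cea = 1)) {
  stopifnot(inherits(config, "synth_config"),
            inherits(subset, "ncd_catalog"))
  if (nrow(subset) == 0L)
    stop("catalog subset is empty", call. = FALSE)
  n <- nrow(subset)
  claims <- gen_claims(config)
  summ <- aggregate_admissions(claims)
  c4 <- criterion4_scores(summ, subset)
  restore <- .Random.seed_guard(config$seed + 2L)
  on.exit(restore())
  draw <- function(crit)
    stats::rlnorm(n, config$lognormal_meanlog[[crit]],
                  config$lognormal_sdlog[[crit]])
  ce <- tier_values[subset$ce_tier]
  if (anyNA(ce))
    stop("catalog subset contains items without a quantifiable",
         " cost-effectiveness tier: ",
         paste(subset$code[is.na(ce)], collapse = ", "), call. = FALSE)
  m <- cbind(people_affected = draw("people_affected"),
             cost_effectiveness = as.numeric(ce),
             attributable_burden = draw("attributable_burden"),
             hospitalization = as.numeric(c4),
             income_inequity = draw("income_inequity"))
  rownames(m) <- subset$code
  m
}
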