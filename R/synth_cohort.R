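# Synthetic patient cohorts: paired (SMI quotient, CD34 fraction)
# outcomes with a tunable latent Spearman correlation, benign/malignant
# group shifts, and covariates (age, BMI, nodule length).

# moment-matched marginals with the right support: Gamma for the
# positive quotient, Beta for the [0,1] CD34 fraction
gamma_par <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) vq_stop("gamma mean and sd must be > 0",
                                    "vq_domain_error")
  list(shape = (mean / sd)^2, rate = mean / sd^2)
}

beta_par <- function(mean, sd) {
  v <- sd^2
  if (mean <= 0 || mean >= 1 || v <= 0 || v >= mean * (1 - mean)) {
    vq_stop("beta mean/sd outside the feasible region", "vq_domain_error")
  }
  k <- mean * (1 - mean) / v - 1
  list(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Specification of a synthetic study cohort
#'
#' Per-patient benign/malignant labels, covariates, and a paired
#' (vascularization quotient, CD34 fraction) outcome generated through a
#' Gaussian copula whose correlation parameter is sin-transformed so
#' that `latent_spearman_rho` is the population Spearman (not Pearson)
#' coefficient of the pair.  Marginals are moment-matched Gamma
#' (quotient, support > 0) and Beta (CD34 fraction, support \[0, 1\])
#' distributions, so empirical group means and SDs converge to the
#' specified values.
#'
#' Defaults reproduce the study conditions of the motivating cohort:
#' 13 benign / 3 malignant nodules; quotient (area-fraction) group means
#' 0.88 +/- 0.89 vs 1.13 +/- 0.19; CD34 100x fraction group means
#' 0.05 +/- 0.05 vs 0.08 +/- 0.06; age 39.75 +/- 12.74 years; BMI
#' 26.08 +/- 5.18 kg/m^2; nodule lengths 27.92 mm (benign) and 35 mm
#' (malignant) on average.
#'
#' @param n_benign,n_malignant group sizes (total >= 2).
#' @param latent_spearman_rho target Spearman correlation of the outcome
#'   pair within each group, in \[-1, 1\].
#' @param benign_quotient_mean,benign_quotient_sd,malignant_quotient_mean,malignant_quotient_sd
#'   group moments of the quotient outcome.
#' @param benign_cd34_mean,benign_cd34_sd,malignant_cd34_mean,malignant_cd34_sd
#'   group moments of the CD34 fraction outcome.
#' @param age_mean,age_sd,bmi_mean,bmi_sd covariate moments.
#' @param benign_length_mean,malignant_length_mean,length_sd nodule
#'   length moments in mm.
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_benign = 13L, n_malignant = 3L,
                        latent_spearman_rho = 0.556,
                        benign_quotient_mean = 0.88,
                        benign_quotient_sd = 0.89,
                        malignant_quotient_mean = 1.13,
                        malignant_quotient_sd = 0.19,
                        benign_cd34_mean = 0.05,
                        benign_cd34_sd = 0.05,
                        malignant_cd34_mean = 0.08,
                        malignant_cd34_sd = 0.06,
                        age_mean = 39.75, age_sd = 12.74,
                        bmi_mean = 26.08, bmi_sd = 5.18,
                        benign_length_mean = 27.92,
                        malignant_length_mean = 35,
                        length_sd = 10,
                        seed = 1L) {
  if (abs(latent_spearman_rho) > 1) {
    vq_stop("|latent_spearman_rho| must be <= 1", "vq_domain_error")
  }
  if (n_benign < 0 || n_malignant < 0 || n_benign + n_malignant < 2) {
    vq_stop("need at least two patients in total", "vq_input_error")
  }
  # validate marginal feasibility up front
  gamma_par(benign_quotient_mean, benign_quotient_sd)
  gamma_par(malignant_quotient_mean, malignant_quotient_sd)
  beta_par(benign_cd34_mean, benign_cd34_sd)
  beta_par(malignant_cd34_mean, malignant_cd34_sd)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws, per patient, a bivariate standard normal pair with Pearson
#' correlation `2 * sin(pi * rho_s / 6)` (the exact inverse of the
#' normal-copula Spearman map), pushes it through the group's Gamma and
#' Beta quantile functions, and attaches covariates.  With
#' `latent_spearman_rho = 1` the two outcomes are comonotone, so their
#' sample Spearman correlation is exactly 1.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `patient_id`, `label`
#'   (benign/malignant), `age`, `bmi`, `length_mm`, `quotient`,
#'   `cd34_fraction`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_benign + spec$n_malignant
  label <- rep(c("benign", "malignant"), c(spec$n_benign, spec$n_malignant))
  rho_p <- 2 * sin(pi * spec$latent_spearman_rho / 6)
  with_seed(spec$seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho_p * z1 + sqrt(max(0, 1 - rho_p^2)) * stats::rnorm(n)
    u1 <- stats::pnorm(z1)
    u2 <- stats::pnorm(z2)
    quo <- numeric(n); cd <- numeric(n); len <- numeric(n)
    for (grp in c("benign", "malignant")) {
      i <- label == grp
      if (!any(i)) next
      gp <- if (grp == "benign") {
        list(q = gamma_par(spec$benign_quotient_mean, spec$benign_quotient_sd),
             c = beta_par(spec$benign_cd34_mean, spec$benign_cd34_sd),
             lm = spec$benign_length_mean)
      } else {
        list(q = gamma_par(spec$malignant_quotient_mean,
                           spec$malignant_quotient_sd),
             c = beta_par(spec$malignant_cd34_mean, spec$malignant_cd34_sd),
             lm = spec$malignant_length_mean)
      }
      quo[i] <- stats::qgamma(u1[i], shape = gp$q$shape, rate = gp$q$rate)
      cd[i] <- stats::qbeta(u2[i], gp$c$shape1, gp$c$shape2)
      len[i] <- pmax(1, stats::rnorm(sum(i), gp$lm, spec$length_sd))
    }
    data.frame(patient_id = sprintf("P%03d", seq_len(n)),
               label = label,
               age = pmax(18, stats::rnorm(n, spec$age_mean, spec$age_sd)),
               bmi = pmax(12, stats::rnorm(n, spec$bmi_mean, spec$bmi_sd)),
               length_mm = len,
               quotient = quo,
               cd34_fraction = cd,
               stringsAsFactors = FALSE)
  })
}
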