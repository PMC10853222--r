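# Synthetic multi-syndrome methylation cohorts.
#
# Beta values are simulated probe-wise: a bimodal baseline (array-wide beta
# distributions are concentrated near 0 and 1), a case effect injected on the
# logit scale and calibrated so the expected case-control difference at the
# probe's baseline equals the configured delta-beta, Gaussian logit-scale
# noise, and linear covariate (age / sex / cell composition) effects added on
# the beta scale before truncation to [0, 1].

#' Describe one syndrome of a synthetic cohort
#'
#' @param name Syndrome label (unique within a cohort).
#' @param n_cases Number of pathogenic-variant carriers in the validation set.
#' @param n_signature_probes Number of CpG probes carrying the episignature
#'   effect.
#' @param delta_beta Target mean case-control beta difference per signature
#'   probe (fraction in `[0, 0.5]`; per-probe sign set by `direction_mix`).
#' @param direction_mix Fraction of signature probes that are
#'   hyper-methylated in cases (the rest are hypo-methylated).
#' @param fraction_intermediate Fraction of cases carrying a 50%-attenuated
#'   ("milder") methylation profile.
#' @param x_linked Is the gene X-linked? Female carriers then present an
#'   attenuated episignature.
#' @param female_attenuation Effect multiplier in `[0, 1]` applied to female
#'   carriers of an X-linked syndrome.
#' @return A `syndrome_spec` list.
#' @export
syndrome_spec <- function(name, n_cases = 10L, n_signature_probes = 120L,
                          delta_beta = 0.15, direction_mix = 0.5,
                          fraction_intermediate = 0, x_linked = FALSE,
                          female_attenuation = 0.5) {
  stop_if(!is.character(name) || length(name) != 1L || !nzchar(name),
          "'name' must be a non-empty string")
  stop_if(n_cases < 0 || n_signature_probes < 0, "counts must be >= 0")
  stop_if(abs(delta_beta) > 0.5, "|delta_beta| must be <= 0.5")
  stop_if(direction_mix < 0 || direction_mix > 1, "'direction_mix' must be in [0, 1]")
  stop_if(fraction_intermediate < 0 || fraction_intermediate > 1,
          "'fraction_intermediate' must be in [0, 1]")
  stop_if(female_attenuation < 0 || female_attenuation > 1,
          "'female_attenuation' must be in [0, 1]")
  structure(list(name = name, n_cases = as.integer(n_cases),
                 n_signature_probes = as.integer(n_signature_probes),
                 delta_beta = delta_beta, direction_mix = direction_mix,
                 fraction_intermediate = fraction_intermediate,
                 x_linked = x_linked, female_attenuation = female_attenuation),
            class = "syndrome_spec")
}

#' Configure a synthetic methylation cohort
#'
#' Defaults reproduce the structure of a typical multi-syndrome validation
#' design: ~10 carriers per syndrome (see [syndrome_spec()]), 25 unaffected
#' controls, linear age / sex / cell-composition confounding and a small
#' detection-failure rate.
#'
#' @param syndromes List of [syndrome_spec()] objects (unique names).
#' @param n_background_probes Number of non-signature probes.
#' @param n_controls Number of unaffected controls.
#' @param n_vus_per_syndrome Number of VUS carriers simulated per syndrome,
#'   drawn from `vus_mixture`.
#' @param confounder_effects Named numeric vector `c(age=, sex=, cell=)` of
#'   slopes on the beta scale: per year of age, for male vs female sex, and
#'   per unit of the first cell fraction.
#' @param noise_sd Standard deviation of probe-level Gaussian noise on the
#'   logit scale.
#' @param detection_fail_rate Probability that a probe x sample detection
#'   p-value exceeds 0.01.
#' @param seed Integer seed; identical configs yield bit-identical cohorts.
#' @param age_range Range (years) of the uniform age distribution.
#' @param case_age_shift Years added to case ages; nonzero values create a
#'   deliberate age imbalance between cases and controls, useful to probe
#'   confounder leakage.
#' @param vus_mixture Named weights `c(full=, half=, null=)` for the latent
#'   effect of VUS carriers (full episignature, 50% intermediate profile, or
#'   benign/no effect).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(syndromes, n_background_probes = 1000L,
                          n_controls = 25L, n_vus_per_syndrome = 0L,
                          confounder_effects = c(age = 0.002, sex = 0.02, cell = 0.10),
                          noise_sd = 0.3, detection_fail_rate = 0.002,
                          seed = 1L, age_range = c(2, 40), case_age_shift = 0,
                          vus_mixture = c(full = 1, half = 1, null = 1) / 3) {
  if (inherits(syndromes, "syndrome_spec")) syndromes <- list(syndromes)
  stop_if(!all(vapply(syndromes, inherits, logical(1), "syndrome_spec")),
          "'syndromes' must be a list of syndrome_spec objects")
  nm <- vapply(syndromes, `[[`, character(1), "name")
  stop_if(anyDuplicated(nm) > 0L, "syndrome names must be unique")
  stop_if(n_background_probes < 0 || n_controls < 0 || n_vus_per_syndrome < 0,
          "counts must be >= 0")
  stop_if(noise_sd <= 0, "'noise_sd' must be > 0")
  stop_if(detection_fail_rate < 0 || detection_fail_rate > 1,
          "'detection_fail_rate' must be in [0, 1]")
  ce <- c(age = 0, sex = 0, cell = 0)
  ce[names(confounder_effects)] <- confounder_effects
  structure(list(syndromes = syndromes,
                 n_background_probes = as.integer(n_background_probes),
                 n_controls = as.integer(n_controls),
                 n_vus_per_syndrome = as.integer(n_vus_per_syndrome),
                 confounder_effects = ce, noise_sd = noise_sd,
                 detection_fail_rate = detection_fail_rate,
                 seed = as.integer(seed), age_range = age_range,
                 case_age_shift = case_age_shift,
                 vus_mixture = vus_mixture / sum(vus_mixture)),
            class = "cohort_config")
}

# Baseline probe means: low / high / intermediate methylation states.
.baseline_background <- function(n) {
  state <- sample.int(3L, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  mu <- numeric(n)
  mu[state == 1L] <- stats::rbeta(sum(state == 1L), 2, 18)   # unmethylated
  mu[state == 2L] <- stats::rbeta(sum(state == 2L), 18, 2)   # methylated
  mu[state == 3L] <- stats::rbeta(sum(state == 3L), 8, 8)    # intermediate
  pmin(pmax(mu, 1e-4), 1 - 1e-4)
}

# Signature probes need headroom for a +/- delta shift on the beta scale.
.baseline_signature <- function(n, delta) {
  lo <- abs(delta) + 0.05
  mu <- stats::rbeta(n, 5, 5)
  pmin(pmax(mu, lo), 1 - lo)
}

#' Generate a synthetic multi-syndrome methylation cohort
#'
#' Simulates a probes x samples beta matrix, a sample sheet with covariates,
#' one episignature probe-list per syndrome and a detection-p-value matrix.
#' Case effects are injected on the logit scale, calibrated per probe so the
#' noise-free case-control beta difference equals the configured
#' `delta_beta`; intermediate-profile cases carry half the effect, female
#' carriers of X-linked syndromes a `female_attenuation` multiple. Covariates
#' act linearly on the beta scale (centered), after which values are
#' truncated to `[0, 1]`.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `betas` (probes x
#'   samples matrix), `sheet` (sample-sheet `data.frame`, including the
#'   latent `true_effect` simulation ground truth), `signatures` (list of
#'   episignature definitions, see [episignature()]) and `detp` (detection
#'   p-value matrix).
#' @export
generate_cohort <- function(config) {
  stop_if(!inherits(config, "cohort_config"), "'config' must be a cohort_config")
  withr::with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(config) {
  syn <- config$syndromes
  n_sig <- vapply(syn, `[[`, integer(1), "n_signature_probes")
  n_probes <- config$n_background_probes + sum(n_sig)
  stop_if(sum(n_sig) > n_probes, "signature probe sets exceed total probe count")
  probe_ids <- sprintf("cg%08d", seq_len(n_probes))

  # Per-probe baselines and per-syndrome signed target deltas.
  mu <- numeric(n_probes)
  mu[seq_len(config$n_background_probes)] <-
    .baseline_background(config$n_background_probes)
  delta <- numeric(n_probes)          # signed target delta per probe
  owner <- integer(n_probes)          # syndrome index owning each probe (0 = none)
  offset <- config$n_background_probes
  signatures <- vector("list", length(syn))
  for (s in seq_along(syn)) {
    idx <- offset + seq_len(n_sig[s])
    offset <- offset + n_sig[s]
    mu[idx] <- .baseline_signature(n_sig[s], syn[[s]]$delta_beta)
    n_hyper <- round(syn[[s]]$direction_mix * n_sig[s])
    sgn <- rep(c(1, -1), c(n_hyper, n_sig[s] - n_hyper))
    delta[idx] <- sgn * syn[[s]]$delta_beta
    owner[idx] <- s
    signatures[[s]] <- episignature(
      name = syn[[s]]$name, syndrome = syn[[s]]$name,
      probe_ids = probe_ids[idx], source = "synthetic",
      x_linked = syn[[s]]$x_linked)
  }
  # Logit-scale shift reproducing delta at the probe baseline (noise-free).
  shift <- ifelse(delta != 0, stats::qlogis(mu + delta) - stats::qlogis(mu), 0)

  # Samples: controls, then cases and VUS per syndrome.
  mk <- function(role, syndrome, effect) data.frame(
    role = role, syndrome = rep_len(syndrome, length(role)),
    true_effect = effect, stringsAsFactors = FALSE)
  parts <- list(mk(rep("control", config$n_controls), NA_character_,
                   rep(0, config$n_controls)))
  for (s in seq_along(syn)) {
    nc <- syn[[s]]$n_cases
    if (nc > 0L) {
      n_int <- round(syn[[s]]$fraction_intermediate * nc)
      eff <- rep(1, nc)
      if (n_int > 0L) eff[sample.int(nc, n_int)] <- 0.5
      parts[[length(parts) + 1L]] <- mk(rep("case", nc), syn[[s]]$name, eff)
    }
    nv <- config$n_vus_per_syndrome
    if (nv > 0L) {
      cls <- sample(c("full", "half", "null"), nv, replace = TRUE,
                    prob = config$vus_mixture)
      eff <- c(full = 1, half = 0.5, null = 0)[cls]
      parts[[length(parts) + 1L]] <- mk(rep("vus", nv), syn[[s]]$name, eff)
    }
  }
  sheet <- do.call(rbind, parts)
  n_samples <- nrow(sheet)
  if (n_samples > 0L) {
    prefix <- ifelse(sheet$role == "control", "control",
                     ifelse(sheet$role == "vus",
                            paste0(sheet$syndrome, "_VUS"), sheet$syndrome))
    sheet$sample_id <- sprintf(
      "%s_%02d", prefix,
      stats::ave(seq_len(n_samples),
                 paste(sheet$role, sheet$syndrome), FUN = seq_along))
    sheet$sex <- sample(c("M", "F"), n_samples, replace = TRUE)
    sheet$age_years <- stats::runif(n_samples, config$age_range[1L],
                                    config$age_range[2L]) +
      ifelse(sheet$role == "case", config$case_age_shift, 0)
    # Controls are age- and sex-matched to the cases: each control mirrors a
    # randomly chosen case's sex and jittered age (unless an age imbalance
    # is requested via case_age_shift, which is left intact).
    is_ctl <- sheet$role == "control"
    is_case <- sheet$role == "case"
    if (any(is_ctl) && any(is_case) && config$case_age_shift == 0) {
      ref <- sample(which(is_case), sum(is_ctl), replace = TRUE)
      sheet$sex[is_ctl] <- sheet$sex[ref]
      sheet$age_years[is_ctl] <- pmax(sheet$age_years[ref] +
                                        stats::rnorm(sum(is_ctl), 0, 2),
                                      config$age_range[1L])
    }
    # 6-part blood cell composition from a Dirichlet distribution.
    alpha <- c(8, 4, 3, 2, 2, 1)
    g <- matrix(stats::rgamma(n_samples * 6L, shape = rep(alpha, each = n_samples)),
                nrow = n_samples)
    frac <- g / rowSums(g)
    colnames(frac) <- paste0("cell_frac_", 1:6)
    sheet <- cbind(sheet, as.data.frame(frac))
    sheet$batch <- sample(paste0("chip", 1:2), n_samples, replace = TRUE)
  } else {
    sheet$sample_id <- character()
    sheet$sex <- character(); sheet$age_years <- numeric()
    for (j in 1:6) sheet[[paste0("cell_frac_", j)]] <- numeric()
    sheet$batch <- character()
  }
  sheet <- sheet[, c("sample_id", "role", "syndrome", "sex", "age_years",
                     paste0("cell_frac_", 1:6), "batch", "true_effect")]
  rownames(sheet) <- NULL

  # Per-sample effect multiplier on each probe's logit shift.
  mult <- matrix(0, nrow = n_probes, ncol = n_samples)
  for (s in seq_along(syn)) {
    carriers <- which(sheet$role %in% c("case", "vus") &
                        sheet$syndrome == syn[[s]]$name)
    if (!length(carriers)) next
    m <- sheet$true_effect[carriers]
    if (syn[[s]]$x_linked)
      m <- m * ifelse(sheet$sex[carriers] == "F", syn[[s]]$female_attenuation, 1)
    mult[owner == s, carriers] <- rep(m, each = sum(owner == s))
  }

  eta <- matrix(rep(stats::qlogis(mu), n_samples), n_probes, n_samples) +
    shift * mult +
    matrix(stats::rnorm(n_probes * n_samples, sd = config$noise_sd),
           n_probes, n_samples)
  betas <- eta
  betas[] <- stats::plogis(eta)
  if (n_samples > 0L) {
    ce <- config$confounder_effects
    cov_shift <- ce[["age"]] * (sheet$age_years - mean(config$age_range)) +
      ce[["sex"]] * (as.numeric(sheet$sex == "M") - 0.5) +
      ce[["cell"]] * (sheet$cell_frac_1 - alpha[1L] / sum(alpha))
    betas <- betas + matrix(cov_shift, n_probes, n_samples, byrow = TRUE)
  }
  betas[] <- pmin(pmax(betas, 0), 1)
  dimnames(betas) <- list(probe_ids, sheet$sample_id)

  fail <- matrix(stats::runif(n_probes * n_samples) < config$detection_fail_rate,
                 n_probes, n_samples)
  detp <- matrix(stats::runif(n_probes * n_samples, 0, 0.01),
                 n_probes, n_samples)
  detp[fail] <- stats::runif(sum(fail), 0.01 + 1e-9, 1)
  dimnames(detp) <- dimnames(betas)

  structure(list(betas = betas, sheet = sheet, signatures = signatures,
                 detp = detp, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic methylation cohort: %d probes x %d samples\n",
              nrow(x$betas), ncol(x$betas)))
  cat(sprintf("  %d controls, %d cases, %d VUS; %d episignatures\n",
              sum(x$sheet$role == "control"), sum(x$sheet$role == "case"),
              sum(x$sheet$role == "vus"), length(x$signatures)))
  invisible(x)
}
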