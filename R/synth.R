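#' Configuration of the synthetic cohort generator
#'
#' Describes the statistical world the generator draws from: a zero-inflated
#' mixture for per-patient maximum diameter stenosis, a log-linear link from
#' stenosis to plaque burden (percent atheroma volume, PAV), a logistic
#' ischemia model on (stenosis, PAV), and the selective referral protocol in
#' which only patients whose *visual* stenosis estimate reaches the referral
#' cutoff undergo PET perfusion imaging. Patients never referred are labelled
#' non-ischemic by the composite reference standard, regardless of their
#' latent state — the verification-bias structure of a CTA-gatekeeper
#' registry.
#'
#' Defaults emulate a registry of 2145 symptomatic patients with 17%
#' reference-positive prevalence, roughly 23% obstructive (stenosis >= 50%)
#' disease by quantitative CT, and roughly 36% referral to PET driven by an
#' upward-biased prompt visual stenosis reading.
#'
#' @param n_patients cohort size (positive integer).
#' @param stenosis_dist list with `minimal_fraction` (probability of the
#'   no/minimal-disease component, in `[0,1]`), `minimal_max` (upper bound of
#'   the minimal component, percent), `location` and `scale` of the diseased
#'   truncated-normal component on `[0,100]` percent.
#' @param pav_link list with `intercept`, `slope` and `noise_sd` of the
#'   log-linear model `log(PAV + epsilon) = intercept + slope * stenosis +
#'   N(0, noise_sd)`, plus `epsilon` (default 0.1).
#' @param ischemia_coef named numeric vector `c(intercept, stenosis, pav)` of
#'   the logistic latent-ischemia model (log-odds scale, per percent).
#' @param plaque_split list with Beta shape parameters `shape1`, `shape2` of
#'   the calcified fraction of PAV (CPV = fraction * PAV, NCPV the rest).
#' @param visual_referral_cutoff percent stenosis above which the visual
#'   reading triggers PET referral; in `(0,100)`, default 50.
#' @param visual_bias mean overestimation (percent) of the prompt visual
#'   stenosis reading relative to quantitative stenosis.
#' @param visual_noise_sd standard deviation (percent) of visual misreading
#'   noise.
#' @param label_mode `"logistic"` (latent ischemia from the logistic model)
#'   or `"planted"` (latent ischemia is a noisy copy of `planted_rule`).
#' @param planted_rule a [staged_rule()] used when `label_mode = "planted"`.
#' @param planted_flip_prob label-noise probability in planted mode: each
#'   latent label independently disagrees with the planted rule with this
#'   probability (0 gives noiseless, perfectly recoverable labels).
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#'
#' @return an object of class `generator_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
generator_config <- function(n_patients = 2145,
                             stenosis_dist = list(minimal_fraction = 0.40,
                                                  minimal_max = 10,
                                                  location = 42,
                                                  scale = 25),
                             pav_link = list(intercept = 0.13,
                                             slope = 0.041,
                                             noise_sd = 0.7,
                                             epsilon = 0.1),
                             ischemia_coef = c(intercept = -5.1,
                                               stenosis = 0.06,
                                               pav = 0.11),
                             plaque_split = list(shape1 = 1.5, shape2 = 4.5),
                             visual_referral_cutoff = 50,
                             visual_bias = 12,
                             visual_noise_sd = 7,
                             label_mode = c("logistic", "planted"),
                             planted_rule = NULL,
                             planted_flip_prob = 0.1,
                             seed = 1L) {
  label_mode <- match.arg(label_mode)
  cfg <- list(n_patients = n_patients,
              stenosis_dist = stenosis_dist,
              pav_link = pav_link,
              ischemia_coef = ischemia_coef,
              plaque_split = plaque_split,
              visual_referral_cutoff = visual_referral_cutoff,
              visual_bias = visual_bias,
              visual_noise_sd = visual_noise_sd,
              label_mode = label_mode,
              planted_rule = planted_rule,
              planted_flip_prob = planted_flip_prob,
              seed = seed)
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  check_scalar_number(cfg$n_patients, "n_patients", lower = 1, integer = TRUE)
  sd_ <- cfg$stenosis_dist
  check_scalar_number(sd_$minimal_fraction, "stenosis_dist$minimal_fraction",
                      lower = 0, upper = 1)
  check_scalar_number(sd_$minimal_max, "stenosis_dist$minimal_max",
                      lower = 0, upper = 100, open_lower = TRUE)
  check_scalar_number(sd_$location, "stenosis_dist$location")
  check_scalar_number(sd_$scale, "stenosis_dist$scale",
                      lower = 0, open_lower = TRUE)
  pl <- cfg$pav_link
  check_scalar_number(pl$intercept, "pav_link$intercept")
  check_scalar_number(pl$slope, "pav_link$slope")
  check_scalar_number(pl$noise_sd, "pav_link$noise_sd", lower = 0)
  cfg$pav_link$epsilon <- pl$epsilon %||% 0.1
  check_scalar_number(cfg$pav_link$epsilon, "pav_link$epsilon",
                      lower = 0, open_lower = TRUE)
  ic <- cfg$ischemia_coef
  if (!is.numeric(ic) || length(ic) != 3L || any(is.na(ic)))
    stop_field("ischemia_coef", "must be 3 numbers (intercept, stenosis, pav)")
  if (any(!is.finite(ic[2:3])))
    stop_field("ischemia_coef", "slope coefficients must be finite")
  ps <- cfg$plaque_split
  check_scalar_number(ps$shape1, "plaque_split$shape1", lower = 0, open_lower = TRUE)
  check_scalar_number(ps$shape2, "plaque_split$shape2", lower = 0, open_lower = TRUE)
  check_scalar_number(cfg$visual_referral_cutoff, "visual_referral_cutoff",
                      lower = 0, upper = 100,
                      open_lower = TRUE, open_upper = TRUE)
  check_scalar_number(cfg$visual_bias, "visual_bias")
  check_scalar_number(cfg$visual_noise_sd, "visual_noise_sd", lower = 0)
  if (cfg$label_mode == "planted") {
    if (is.null(cfg$planted_rule) || !inherits(cfg$planted_rule, "staged_rule"))
      stop_field("planted_rule", "must be a staged_rule when label_mode = 'planted'")
    check_scalar_number(cfg$planted_flip_prob, "planted_flip_prob",
                        lower = 0, upper = 1)
  }
  check_scalar_number(cfg$seed, "seed", integer = TRUE)
  structure(cfg, class = "generator_config")
}

# Number of uniform variates consumed per patient record. All draws go
# through inverse-CDF transforms of a single runif() stream so that record i
# always consumes positions (i-1)*K+1 .. i*K: records are order-independent
# and the first i records are identical for any n >= i.
.SYNTH_DRAWS_PER_RECORD <- 7L

#' Generate a synthetic CTA/PET cohort
#'
#' Draws one patient per row from the world described by a
#' [generator_config()]: quantitative stenosis from a zero-inflated mixture,
#' PAV from the log-linear link, latent ischemia from the logistic (or
#' planted-rule) model, a noisy visual stenosis reading deciding PET
#' referral, and the composite reference label
#' `ischemia = latent_ischemia & pet_performed`.
#'
#' @param config a [generator_config()].
#' @return a `data.frame` with columns `patient_id`, `stenosis`, `pav`,
#'   `ncpv`, `cpv` (percent), `pet_performed`, `ischemia` and
#'   `latent_ischemia` (logical). `latent_ischemia` is the simulation truth,
#'   retained so that verification-bias experiments remain possible; it is
#'   absent from the CSV interchange schema.
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 500, seed = 7))
#' mean(cohort$ischemia)
#' @export
generate_cohort <- function(config) {
  config <- validate_generator_config(unclass(config))
  n <- as.integer(config$n_patients)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(config$seed))
  U <- matrix(stats::runif(n * .SYNTH_DRAWS_PER_RECORD),
              nrow = n, ncol = .SYNTH_DRAWS_PER_RECORD, byrow = TRUE)

  sd_ <- config$stenosis_dist
  minimal <- U[, 1L] < sd_$minimal_fraction
  # truncated normal on [0, 100] by inverse CDF
  p_lo <- stats::pnorm(0, sd_$location, sd_$scale)
  p_hi <- stats::pnorm(100, sd_$location, sd_$scale)
  stenosis <- ifelse(minimal,
                     sd_$minimal_max * U[, 2L],
                     stats::qnorm(p_lo + U[, 2L] * (p_hi - p_lo),
                                  sd_$location, sd_$scale))
  stenosis <- pmin(pmax(stenosis, 0), 100)

  pl <- config$pav_link
  pav <- exp(pl$intercept + pl$slope * stenosis +
               stats::qnorm(U[, 3L]) * pl$noise_sd) - pl$epsilon
  pav <- pmin(pmax(pav, 0), 100)

  calc_frac <- stats::qbeta(U[, 4L], config$plaque_split$shape1,
                            config$plaque_split$shape2)
  cpv <- pav * calc_frac
  ncpv <- pav - cpv

  latent <- if (config$label_mode == "logistic") {
    ic <- as.numeric(config$ischemia_coef)
    U[, 5L] < expit(ic[1L] + ic[2L] * stenosis + ic[3L] * pav)
  } else {
    planted <- classify_staged(stenosis, pav, config$planted_rule)
    xor(planted, U[, 5L] < config$planted_flip_prob)
  }

  visual <- stenosis + config$visual_bias +
    stats::qnorm(U[, 6L]) * config$visual_noise_sd
  visual <- pmin(pmax(visual, 0), 100)
  pet_performed <- visual >= config$visual_referral_cutoff
  ischemia <- latent & pet_performed

  data.frame(patient_id = sprintf("P%05d", seq_len(n)),
             stenosis = stenosis,
             pav = pav,
             ncpv = ncpv,
             cpv = cpv,
             pet_performed = pet_performed,
             ischemia = ischemia,
             latent_ischemia = latent,
             stringsAsFactors = FALSE)
}

#' Percent atheroma volume from raw volumes
#'
#' Plaque burden normalization: total plaque volume divided by vessel volume,
#' expressed in percent.
#'
#' @param total_plaque_volume total plaque volume, mm^3.
#' @param vessel_volume vessel volume, mm^3; must be positive and at least
#'   `total_plaque_volume`.
#' @return percent atheroma volume in `[0, 100]`.
#' @examples
#' compute_pav(157, 1000) # 15.7
#' @export
compute_pav <- function(total_plaque_volume, vessel_volume) {
  if (!is.numeric(total_plaque_volume) || !is.numeric(vessel_volume))
    stop("volumes must be numeric", call. = FALSE)
  if (any(vessel_volume <= 0))
    stop_field("vessel_volume", "must be > 0")
  if (any(total_plaque_volume < 0) || any(total_plaque_volume > vessel_volume))
    stop_field("total_plaque_volume",
               "must lie in [0, vessel_volume]")
  100 * total_plaque_volume / vessel_volume
}
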