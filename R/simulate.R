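#' Synthetic cohort generation
#'
#' Generates patient, provider and healthy-control cohorts, plus retest
#' waves, with the statistical structure the audit pipeline assumes, so the
#' whole analysis can be exercised without the original registry data (which
#' are not deposited).
#'
#' Knowledge responses follow a latent-trait threshold model: each
#' respondent carries a standard-normal knowledge trait, each
#' respondent-by-part combination a stable person-item knowledge residual,
#' and each wave an independent measurement disturbance; the three loadings
#' square-sum to one, so per-part marginal correct probabilities are set
#' directly per group (the five published items from their printed response
#' counts, the rest calibrated). The trait loading controls the score
#' spread, the stable loading the test-retest reliability, and the wave
#' loading the retest noise; one deliberately reverse-keyed item gives the
#' item-retention diagnostics a negative item-total correlation to find.
#'
#' Goal ratings come from a six-dimensional latent normal vector (plus two
#' independent placeholder goals), with per-wave measurement noise, rounded
#' and clipped to the 0-10 grid; the strong ceiling of the recurrence
#' concern is produced by a latent mean above 10, not a point mass. Goals
#' are generated first and treatment second: mastectomy is drawn
#' Bernoulli(logistic(b0 + b'x)) from the observed (discretized) test-wave
#' goal ratings and stage, so the analysis model family coincides with the
#' generative family and simulate-and-refit is a fair parameter-recovery
#' test. A configured number of patients report no definitive surgery and a
#' configured fraction had lumpectomy followed by mastectomy (clinically
#' forced treatment); both are excluded from the concordance model
#' downstream. Missingness is applied after outcomes are drawn; the
#' remove-breast goal's missingness is concentrated among lumpectomy
#' patients, as observed.
#'
#' @name synthetic_cohort
NULL

#' Default generator configuration
#'
#' Defaults encode the published study conditions: group sizes 440/88/35,
#' per-item correct-response profiles for the five published items from
#' their printed counts, treatment-model coefficients equal to the logs of
#' the published multivariable odds ratios (0.79 keep breast, 1.88 remove
#' breast, 1.23 avoid radiation, 1.81 stage II), stage II prevalence 0.398,
#' 1.4% per-item knowledge missingness, 10.9% missingness on the
#' remove-breast goal with 94% of it among lumpectomy patients and about
#' 3.3% elsewhere, and a retest wave for 100 patients. The free parameters
#' (unpublished item profiles via per-group probit shifts, latent goal means
#' and covariance, loadings, wave noise, intercept) were calibrated with
#' [calibrate_generator()] against the published summaries: group knowledge
#' means 52.7/87.7/49.3 with patient SD 21.8, treatment-arm goal means,
#' keep-remove correlation -0.46, analyzable mastectomy fraction 111/383,
#' retest ICCs (knowledge 0.70; goals 0.87/0.83/0.66/0.76/0.64/0.61), and
#' the emergent concordance/c-statistic checked against 89%/0.95.
#'
#' @return a `dqi_generator_config` list; see source for field meanings.
#' @export
default_generator_config <- function() {
  goal_ids <- c("keep_breast", "remove_breast", "avoid_recurrence",
                "avoid_radiation", "radiation_side_effects", "radiation_hassle")
  # latent goal model: single-factor correlation structure (a
  # mastectomy-leaning attitude loading negatively on keep-breast and
  # positively on the rest), PSD by construction
  sds <- c(4.4691, 6.4491, 2.0000, 5.2000, 2.6000, 3.2000)
  loadings <- c(-0.7166, 0.8200, 0.6000, 0.5594, 0.1760, 0.7122)
  R <- tcrossprod(loadings)
  diag(R) <- 1
  sigma <- diag(sds) %*% R %*% diag(sds)
  dimnames(sigma) <- list(goal_ids, goal_ids)

  mu <- c(keep_breast = 5.8003, remove_breast = 5.3651,
          avoid_recurrence = 11.5542, avoid_radiation = 1.5447,
          radiation_side_effects = 5.7279, radiation_hassle = 2.3810)

  # per-part correct probabilities; published items from printed counts
  profiles <- rbind(
    k01  = c(263 / 437, 85 / 88, 13 / 35),
    k02  = c(312 / 438, 87 / 88, 24 / 35),
    k03  = c(304 / 432, 88 / 88, 30 / 35),
    k04  = c(245 / 433, 84 / 88, 11 / 35),
    k05  = c(202 / 435, 67 / 87, 23 / 35),
    k06  = c(0.300, 0.700, 0.250),
    k07  = c(0.360, 0.780, 0.330),
    k08  = c(0.420, 0.820, 0.380),
    k09  = c(0.470, 0.850, 0.430),
    k10  = c(0.520, 0.870, 0.470),
    k11  = c(0.580, 0.900, 0.520),
    k12a = c(0.580, 0.890, 0.600),
    k12b = c(0.672, 0.938, 0.702),
    k13  = c(0.900, 0.980, 0.920),
    k14  = c(0.860, 0.970, 0.880),
    k15  = c(0.450, 0.550, 0.450))
  colnames(profiles) <- c("patient", "provider", "control")

  structure(list(
    n_patients = 440L, n_providers = 88L, n_controls = 35L,
    n_no_treatment = 28L, frac_lump_then_mast = 29 / 412,
    retest_n = 100L,
    ability = list(trait_loading = 0.46704, stable_loading = 0.39946),
    free_item_shift = c(patient = 0.00153, provider = 0.01763,
                        control = -0.00318),
    item_profiles = profiles,
    fixed_profile_parts = c("k01", "k02", "k03", "k04", "k05"),
    reversed_parts = "k15",
    not_sure_share = 0.45,
    goal_mu = mu, goal_sigma = sigma,
    goal_wave_sd = c(keep_breast = 1.5411, remove_breast = 2.4281,
                     avoid_recurrence = 1.0008, avoid_radiation = 2.4730,
                     radiation_side_effects = 1.8676, radiation_hassle = 2.3571,
                     placeholder_1 = 1.50, placeholder_2 = 1.50),
    extra_goal_mu = c(placeholder_1 = 5.0, placeholder_2 = 4.5),
    extra_goal_sd = c(placeholder_1 = 2.5, placeholder_2 = 2.5),
    treatment = list(
      intercept = -5.3007, stage2 = log(1.81),
      coef = c(keep_breast = log(0.79), remove_breast = log(1.88),
               avoid_recurrence = 0, avoid_radiation = log(1.23),
               radiation_side_effects = 0, radiation_hassle = 0)),
    stage2_prob = 0.398,
    missing = list(knowledge = 0.014,
                   goals = c(keep_breast = 0.015, remove_breast = 0.109,
                             avoid_recurrence = 0.009, avoid_radiation = 0.033,
                             radiation_side_effects = 0.042,
                             radiation_hassle = 0.035,
                             placeholder_1 = 0.030, placeholder_2 = 0.030),
                   remove_breast_lump_share = 0.94),
    preference = list(noise_sd = 1.3, cut_lump = -1.8, cut_mast = -0.1),
    confidence = list(mean = 9.1, sd = 1.4),
    regret_probs = c(definitely_yes = 0.55, probably_yes = 0.33,
                     not_sure = 0.06, probably_no = 0.04,
                     definitely_no = 0.02),
    education_probs = c(hs_or_less = 0.125, some_college = 0.241,
                        college_plus = 0.634),
    control_education_probs = c(hs_or_less = 0.0, some_college = 0.229,
                                college_plus = 0.771),
    completion = list(means = c(hs_or_less = 6.8, some_college = 6.4,
                                college_plus = 5.3),
                      sd = 2.2, min = 1.4, max = 19),
    coverage_probs = c(0.05, 0.19, 0.45, 0.31),
    demographics = list(
      patient_age = c(56.9, 11.3), provider_age = c(45, 9),
      control_age = c(42.4, 10.9),
      race_probs = c(white = 0.830, black = 0.080, other = 0.090),
      income_probs = c(lt30k = 0.134, `30_60k` = 0.198, `60_100k` = 0.243,
                       gt100k = 0.364),
      marital_probs = c(married_partnered = 0.675, other = 0.320,
                        missing = 0.005)),
    generator_version = "bcsdqi-generator 1"),
    class = "dqi_generator_config")
}

validate_generator_config <- function(config) {
  stopifnot(inherits(config, "dqi_generator_config"))
  pr <- config$item_profiles
  if (any(pr < 0 | pr > 1)) stop("item profile probabilities must lie in [0, 1]")
  ab <- config$ability
  if (ab$trait_loading^2 + ab$stable_loading^2 > 1)
    stop("trait and stable loadings must square-sum to at most 1")
  if (any(!is.finite(unlist(config$treatment))))
    stop("treatment coefficients must be finite")
  ev <- eigen(config$goal_sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("goal covariance matrix is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  if (any(unlist(config$missing) < 0 | unlist(config$missing) > 1))
    stop("missingness rates must lie in [0, 1]")
  invisible(config)
}

# applies the per-group probit calibration shift to the free item parts
group_profile <- function(config, group) {
  p <- config$item_profiles[, group]
  free <- setdiff(rownames(config$item_profiles), config$fixed_profile_parts)
  shift <- config$free_item_shift[[group]]
  if (!is.null(shift) && shift != 0)
    p[free] <- stats::pnorm(stats::qnorm(pmin(pmax(p[free], 1e-12), 1 - 1e-12)) + shift)
  p
}

# draw knowledge response tokens for one group given latent components
draw_knowledge <- function(config, bank, group, theta, stable) {
  pt <- bank_parts(bank)
  ab <- config$ability
  omega <- sqrt(max(0, 1 - ab$trait_loading^2 - ab$stable_loading^2))
  prob <- group_profile(config, group)
  n <- length(theta)
  out <- matrix(NA_character_, n, nrow(pt), dimnames = list(NULL, pt$part_id))
  for (j in seq_len(nrow(pt))) {
    pid <- pt$part_id[j]
    sgn <- if (pid %in% config$reversed_parts) -1 else 1
    lat <- sgn * ab$trait_loading * theta + ab$stable_loading * stable[, pid] +
      omega * stats::rnorm(n)
    correct <- lat > stats::qnorm(1 - prob[[pid]])
    it <- bank[[pt$item_id[j]]]
    part <- it$parts[[which(vapply(it$parts, `[[`, character(1), "part_id") == pid)]]
    tok <- character(n)
    if (it$kind == "multiple_choice") {
      n_opt <- length(part$options)
      tok[correct] <- as.character(part$correct)
      nw <- sum(!correct)
      if (nw > 0) {
        ns <- stats::runif(nw) < config$not_sure_share
        wrong_opts <- setdiff(seq_len(n_opt), part$correct)
        pick <- sample(wrong_opts, nw, replace = TRUE)
        tok[!correct] <- ifelse(ns, NOT_SURE, as.character(pick))
      }
    } else {
      lo <- part$correct[1]; hi <- part$correct[2]
      tok[correct] <- as.character(round(stats::runif(sum(correct), lo, hi)))
      nw <- sum(!correct)
      if (nw > 0) {
        ns <- stats::runif(nw) < config$not_sure_share
        below <- stats::runif(nw) < 0.5
        val <- ifelse(below,
                      pmax(0, lo - 1 - round(stats::runif(nw, 0, 0.4 * (hi - lo + 10)))),
                      hi + 1 + round(stats::runif(nw, 0, 0.4 * (hi - lo + 10))))
        tok[!correct] <- ifelse(ns, NOT_SURE, as.character(val))
      }
    }
    out[, j] <- tok
  }
  out
}

apply_knowledge_missing <- function(tokens, rate) {
  drop <- matrix(stats::runif(length(tokens)) < rate, nrow(tokens), ncol(tokens))
  tokens[drop] <- NA_character_
  tokens
}

discretize_goals <- function(latent, wave_sd) {
  noise <- matrix(stats::rnorm(length(latent)), nrow(latent), ncol(latent))
  obs <- latent + sweep(noise, 2, wave_sd[colnames(latent)], `*`)
  pmin(pmax(round(obs), 0), 10)
}

rlnorm_mean <- function(n, m, s) {
  sdlog <- sqrt(log(1 + s^2 / m^2))
  stats::rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
}

empty_records <- function(n, bank, goals) {
  cols <- cohort_columns(bank, goals)
  df <- data.frame(respondent_id = character(n), group = character(n),
                   wave = rep("test", n), treatment = rep("none", n),
                   stage = rep("none", n), preference = rep("none", n),
                   stringsAsFactors = FALSE)
  for (col in cols$parts) df[[col]] <- NA_character_
  for (col in cols$goals) df[[col]] <- NA_real_
  df$confidence <- NA_real_
  df$regret <- NA_character_
  df$top3_1 <- NA_character_; df$top3_2 <- NA_character_; df$top3_3 <- NA_character_
  df$completion_minutes <- NA_real_
  df$education <- NA_character_
  df$coverage_rating <- NA_real_
  df$age <- NA_real_
  df$race <- NA_character_
  df$income <- NA_character_
  df$marital <- NA_character_
  df
}

#' Generate a synthetic cohort
#'
#' @param config a `dqi_generator_config` (default [default_generator_config()]).
#' @param seed integer seed; the generator is fully deterministic given the
#'   seed (Mersenne-Twister / inversion / rejection sampling, recorded in the
#'   cohort provenance).
#' @param bank,goals instrument banks (defaults match the generator).
#' @return a `dqi_cohort` with latent traits retained (needed by
#'   [generate_retest()]).
#' @export
generate_cohort <- function(config = default_generator_config(), seed = 1L,
                            bank = default_item_bank(),
                            goals = default_goal_bank()) {
  validate_generator_config(config)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  pt <- bank_parts(bank)
  n_pat <- config$n_patients
  goal_ids6 <- colnames(config$goal_sigma)

  # ---- patients -----------------------------------------------------------
  pat <- empty_records(n_pat, bank, goals)
  pat$respondent_id <- sprintf("P%04d", seq_len(n_pat))
  pat$group <- "patient"

  theta_p <- stats::rnorm(n_pat)
  stable_p <- matrix(stats::rnorm(n_pat * nrow(pt)), n_pat, nrow(pt),
                     dimnames = list(pat$respondent_id, pt$part_id))

  lat6 <- MASS::mvrnorm(n_pat, mu = config$goal_mu, Sigma = config$goal_sigma)
  colnames(lat6) <- goal_ids6
  extra_ids <- names(config$extra_goal_mu)
  lat_extra <- sapply(extra_ids, function(g)
    stats::rnorm(n_pat, config$extra_goal_mu[[g]], config$extra_goal_sd[[g]]))
  goal_latent <- cbind(lat6, lat_extra)
  goal_obs <- discretize_goals(goal_latent, config$goal_wave_sd)
  for (g in colnames(goal_obs)) pat[[paste0("g_", g)]] <- goal_obs[, g]

  pat$stage <- ifelse(stats::runif(n_pat) < config$stage2_prob, "II", "I")
  lp <- config$treatment$intercept +
    config$treatment$stage2 * (pat$stage == "II") +
    drop(goal_obs[, goal_ids6] %*% config$treatment$coef[goal_ids6])
  p_true <- stats::plogis(lp)
  pat$treatment <- ifelse(stats::runif(n_pat) < p_true, "mastectomy", "lumpectomy")

  # clinically driven exclusions, overriding the model draw
  idx_none <- sample.int(n_pat, config$n_no_treatment)
  n_ltm <- round(config$frac_lump_then_mast * (n_pat - config$n_no_treatment))
  idx_ltm <- sample(setdiff(seq_len(n_pat), idx_none), n_ltm)
  pat$treatment[idx_none] <- "none"
  pat$treatment[idx_ltm] <- "lumpectomy_then_mastectomy"

  ktok <- draw_knowledge(config, bank, "patient", theta_p, stable_p)
  ktok <- apply_knowledge_missing(ktok, config$missing$knowledge)
  for (col in colnames(ktok)) pat[[col]] <- ktok[, col]

  # goal missingness, remove-breast concentrated among lumpectomy patients
  had_lump <- pat$treatment %in% c("lumpectomy", "lumpectomy_then_mastectomy")
  for (g in colnames(goal_obs)) {
    rate <- config$missing$goals[[g]]
    if (g == "remove_breast") {
      share <- config$missing$remove_breast_lump_share
      r_l <- min(1, rate * share * n_pat / max(1, sum(had_lump)))
      r_o <- min(1, rate * (1 - share) * n_pat / max(1, sum(!had_lump)))
      drop <- stats::runif(n_pat) < ifelse(had_lump, r_l, r_o)
    } else {
      drop <- stats::runif(n_pat) < rate
    }
    pat[[paste0("g_", g)]][drop] <- NA_real_
  }

  pref_lat <- stats::qlogis(pmin(pmax(p_true, 1e-12), 1 - 1e-12)) +
    stats::rnorm(n_pat, 0, config$preference$noise_sd)
  pat$preference <- ifelse(pref_lat >= config$preference$cut_mast, "mastectomy",
                    ifelse(pref_lat <= config$preference$cut_lump,
                           "lumpectomy_radiation", "not_sure"))

  pat$confidence <- pmin(10, pmax(0, round(
    stats::rnorm(n_pat, config$confidence$mean, config$confidence$sd))))
  pat$regret <- sample(names(config$regret_probs), n_pat, replace = TRUE,
                       prob = config$regret_probs)

  ratings <- as.matrix(pat[, goal_cols(goals), drop = FALSE])
  tie <- matrix(stats::runif(length(ratings)), nrow(ratings))
  for (i in seq_len(n_pat)) {
    r <- ratings[i, ]
    if (all(is.na(r))) next
    ord <- order(r + tie[i, ], decreasing = TRUE, na.last = NA)
    top <- goals$goal_id[ord][seq_len(min(3, length(ord)))]
    pat[i, c("top3_1", "top3_2", "top3_3")[seq_along(top)]] <- top
  }

  pat$education <- sample(names(config$education_probs), n_pat, replace = TRUE,
                          prob = config$education_probs)
  cm <- config$completion
  pat$completion_minutes <- round(pmin(cm$max, pmax(cm$min, rlnorm_mean(
    n_pat, cm$means[pat$education], cm$sd))), 1)
  dem <- config$demographics
  pat$age <- round(stats::rnorm(n_pat, dem$patient_age[1], dem$patient_age[2]))
  pat$race <- sample(names(dem$race_probs), n_pat, TRUE, dem$race_probs)
  pat$income <- sample(names(dem$income_probs), n_pat, TRUE, dem$income_probs)
  mar <- sample(names(dem$marital_probs), n_pat, TRUE, dem$marital_probs)
  pat$marital <- ifelse(mar == "missing", NA_character_, mar)

  # ---- providers and controls --------------------------------------------
  make_group <- function(n, group, prefix, age_par) {
    df <- empty_records(n, bank, goals)
    df$respondent_id <- sprintf("%s%03d", prefix, seq_len(n))
    df$group <- group
    theta <- stats::rnorm(n)
    stable <- matrix(stats::rnorm(n * nrow(pt)), n, nrow(pt),
                     dimnames = list(df$respondent_id, pt$part_id))
    tok <- apply_knowledge_missing(
      draw_knowledge(config, bank, group, theta, stable),
      config$missing$knowledge)
    for (col in colnames(tok)) df[[col]] <- tok[, col]
    df$age <- round(stats::rnorm(n, age_par[1], age_par[2]))
    list(df = df, theta = theta, stable = stable)
  }
  prov <- make_group(config$n_providers, "provider", "D", config$demographics$provider_age)
  prov$df$coverage_rating <- sample(1:4, config$n_providers, TRUE,
                                    config$coverage_probs)
  ctrl <- make_group(config$n_controls, "control", "C", config$demographics$control_age)
  ctrl$df$education <- sample(names(config$control_education_probs),
                              config$n_controls, TRUE,
                              config$control_education_probs)
  ctrl$df$race <- sample(names(config$demographics$race_probs),
                         config$n_controls, TRUE, config$demographics$race_probs)

  records <- rbind(pat, prov$df, ctrl$df)
  theta <- c(theta_p, prov$theta, ctrl$theta)
  names(theta) <- records$respondent_id
  rownames(goal_latent) <- pat$respondent_id
  new_cohort(records, bank, goals,
             provenance = list(source = "synthetic", seed = as.integer(seed),
                               generator = config$generator_version,
                               rng = paste(RNGkind(), collapse = "/")),
             latents = list(theta = theta,
                            stable = rbind(stable_p, prov$stable, ctrl$stable),
                            goal_latent = goal_latent,
                            p_true = stats::setNames(p_true, pat$respondent_id)))
}

#' Generate a retest wave
#'
#' Re-administers the instrument to a subsample of patients roughly four
#' weeks later: the knowledge trait, stable person-item knowledge and latent
#' goal vector are carried over unchanged; measurement (wave) noise,
#' discretization and missingness are drawn afresh. Only patients are
#' retested.
#'
#' @param cohort a synthetic `dqi_cohort` with latent traits retained.
#' @param config the generator configuration used for the cohort.
#' @param seed integer seed for the retest draws.
#' @param groups groups to retest; anything but `"patient"` is an error.
#' @return a `dqi_cohort` holding the retest-wave records.
#' @export
generate_retest <- function(cohort, config = default_generator_config(),
                            seed = 1L, groups = "patient") {
  if (!identical(groups, "patient"))
    stop("only patients receive a retest survey")
  if (is.null(cohort$latents))
    stop("cohort has no retained latent traits; generate it with generate_cohort()")
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  bank <- cohort$item_bank
  pat <- patients_test(cohort)
  n_sub <- min(config$retest_n, nrow(pat))
  ids <- sort(sample(pat$respondent_id, n_sub))
  sub <- pat[match(ids, pat$respondent_id), , drop = FALSE]
  sub$wave <- "retest"

  theta <- cohort$latents$theta[ids]
  stable <- cohort$latents$stable[ids, , drop = FALSE]
  tok <- apply_knowledge_missing(
    draw_knowledge(config, bank, "patient", theta, stable),
    config$missing$knowledge)
  for (col in colnames(tok)) sub[[col]] <- tok[, col]

  lat <- cohort$latents$goal_latent[ids, , drop = FALSE]
  goal_obs <- discretize_goals(lat, config$goal_wave_sd)
  for (g in colnames(goal_obs)) sub[[paste0("g_", g)]] <- goal_obs[, g]
  for (g in colnames(goal_obs)) {
    rate <- config$missing$goals[[g]]
    drop <- stats::runif(n_sub) < rate
    sub[[paste0("g_", g)]][drop] <- NA_real_
  }
  cm <- config$completion
  sub$completion_minutes <- round(pmin(cm$max, pmax(cm$min, rlnorm_mean(
    n_sub, cm$means[sub$education], cm$sd))), 1)

  new_cohort(sub, bank, cohort$goals,
             provenance = list(source = "synthetic",
                               seed = as.integer(seed),
                               wave = "retest",
                               generator = config$generator_version))
}
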