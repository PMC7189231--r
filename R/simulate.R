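#' Configuration for the synthetic EHR generator
#'
#' Defines the generative model of [generate_corpus()]: a desk-scale stand-in
#' for a primary-care cohort with the statistical structure downstream stages
#' rely on — multi-code visits, disease *groups* with strong within-group
#' co-occurrence and succession, age-dependent group activity, a latent
#' binary attribute (a gender-analog) with attribute-exclusive codes, and
#' irregular inter-visit gaps.
#'
#' @param n_patients Number of patients (default 2000).
#' @param n_codes Number of disease codes `G` (default 60).
#' @param n_groups Number of disease groups (default 6).
#' @param codes_per_group Codes per group; `n_groups * codes_per_group` must
#'   not exceed `n_codes` (default 10).
#' @param attribute_exclusive_fraction Fraction of codes restricted to one
#'   attribute level, split evenly between the levels (default 0.2).
#' @param within_group_affinity Sampling-weight multiplier for codes of the
#'   visit's active group relative to all other codes (default 12).
#' @param group_self_transition Probability that consecutive visits keep the
#'   same active group (default 0.7).
#' @param age_start_distribution `c(mean, sd)` of the age (years) at the first
#'   visit (default `c(45, 15)`).
#' @param visit_gap_distribution `c(mean, sd)` of the positive inter-visit gap
#'   in months (default `c(6, 4)`).
#' @param visits_range `c(min, max)` visits per patient, uniform; the minimum
#'   must be at least 5 so every patient passes cohort inclusion
#'   (default `c(5, 12)`).
#' @param codes_per_visit_range `c(min, max)` distinct codes per visit,
#'   uniform (default `c(1, 4)`).
#' @param age_group_bandwidth Width (years) of the Gaussian kernel tying each
#'   group to its preferred age; group age-centres are spread evenly over
#'   25--85 years (default 15).
#' @param follow_up_months Observation continues this many months past the
#'   last visit (default 18).
#' @param seed Integer RNG seed; identical seeds give byte-identical corpora.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 2000L, n_codes = 60L, n_groups = 6L,
                       codes_per_group = 10L,
                       attribute_exclusive_fraction = 0.2,
                       within_group_affinity = 12,
                       group_self_transition = 0.7,
                       age_start_distribution = c(45, 15),
                       visit_gap_distribution = c(6, 4),
                       visits_range = c(5L, 12L),
                       codes_per_visit_range = c(1L, 4L),
                       age_group_bandwidth = 15,
                       follow_up_months = 18L,
                       seed = 0L) {
  cfg <- list(
    n_patients = as.integer(n_patients), n_codes = as.integer(n_codes),
    n_groups = as.integer(n_groups), codes_per_group = as.integer(codes_per_group),
    attribute_exclusive_fraction = attribute_exclusive_fraction,
    within_group_affinity = within_group_affinity,
    group_self_transition = group_self_transition,
    age_start_distribution = age_start_distribution,
    visit_gap_distribution = visit_gap_distribution,
    visits_range = as.integer(visits_range),
    codes_per_visit_range = as.integer(codes_per_visit_range),
    age_group_bandwidth = age_group_bandwidth,
    follow_up_months = as.integer(follow_up_months),
    seed = as.integer(seed)
  )
  if (cfg$n_groups * cfg$codes_per_group > cfg$n_codes) {
    stop("n_groups * codes_per_group exceeds n_codes", call. = FALSE)
  }
  if (cfg$visits_range[1] < 5L) {
    stop("visits_range minimum must be at least 5 (cohort inclusion)", call. = FALSE)
  }
  if (cfg$attribute_exclusive_fraction < 0 || cfg$attribute_exclusive_fraction > 1 ||
      cfg$group_self_transition < 0 || cfg$group_self_transition > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$codes_per_visit_range[2] > cfg$n_codes) {
    stop("codes_per_visit_range exceeds the number of codes", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic EHR corpus with planted structure
#'
#' Per patient: a latent attribute is drawn uniformly from `{0, 1}`; a start
#' age, visit count and positive month gaps define the visit times. Visit
#' activity follows a first-order Markov chain over disease groups with
#' self-transition bias `group_self_transition`; otherwise the next active
#' group is drawn with weights from a Gaussian age kernel centred on each
#' group's preferred age. Each visit samples distinct codes with weight
#' `within_group_affinity` for the active group's codes and 1 elsewhere,
#' never emitting codes disallowed for the patient's attribute.
#' Observation ends `follow_up_months` after the last visit.
#'
#' Codes are named `Dxx` (`D01 ...`); a fraction of codes in each attribute
#' level is exclusive to that level, emulating gender-restricted diagnoses.
#'
#' @param config A [sim_config()].
#' @return A list with `corpus` (an [ehr_corpus()]; each patient's
#'   `attributes` holds `attribute`) and `ground_truth` (list with
#'   `group_of_code`, a named integer vector, and `allowed_attribute`, a
#'   named vector with values `0`, `1` or `"both"`).
#' @examples
#' out <- generate_corpus(sim_config(n_patients = 10, seed = 42))
#' out$corpus
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gt <- ground_truth_from_config(config)
  codes <- names(gt$group_of_code)
  group_of <- gt$group_of_code
  allowed <- gt$allowed_attribute
  centres <- group_age_centres(config$n_groups)

  withr_seed <- config$seed
  old <- .Random.seed_exists()
  set.seed(withr_seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)

  patients <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    attr_level <- sample(0:1, 1L)
    ok <- allowed == "both" | allowed == as.character(attr_level)
    start_age_months <- max(0L, round(12 * stats::rnorm(
      1, config$age_start_distribution[1], config$age_start_distribution[2])))
    n_visits <- sample(config$visits_range[1]:config$visits_range[2], 1L)
    gaps <- pmax(1L, round(stats::rnorm(
      n_visits - 1L, config$visit_gap_distribution[1], config$visit_gap_distribution[2])))
    ages <- as.integer(start_age_months + cumsum(c(0L, gaps)))

    group <- NA_integer_
    visits <- vector("list", n_visits)
    for (j in seq_len(n_visits)) {
      age_yrs <- ages[[j]] / 12
      kern <- exp(-((age_yrs - centres) / config$age_group_bandwidth)^2)
      if (is.na(group) || stats::runif(1) > config$group_self_transition) {
        group <- sample.int(config$n_groups, 1L, prob = kern)
      }
      w <- ifelse(group_of == group, config$within_group_affinity, 1)
      w[!ok] <- 0
      m <- sample(config$codes_per_visit_range[1]:config$codes_per_visit_range[2], 1L)
      m <- min(m, sum(w > 0))
      drawn <- sample(codes, m, prob = w)
      visits[[j]] <- list(age_months = ages[[j]], codes = sort(drawn))
    }
    patients[[p]] <- list(
      patient_id = sprintf("P%05d", p),
      observation_end_age_months = ages[[n_visits]] + config$follow_up_months,
      attributes = list(attribute = attr_level),
      visits = visits
    )
  }
  list(corpus = ehr_corpus(patients), ground_truth = gt)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

group_age_centres <- function(n_groups) seq(25, 85, length.out = n_groups)

ground_truth_from_config <- function(config) {
  codes <- sprintf("D%02d", seq_len(config$n_codes))
  group_of <- rep(NA_integer_, config$n_codes)
  idx <- 1L
  for (g in seq_len(config$n_groups)) {
    group_of[idx:(idx + config$codes_per_group - 1L)] <- g
    idx <- idx + config$codes_per_group
  }
  # leftover codes (if any) cycle through the groups
  if (idx <= config$n_codes) {
    group_of[idx:config$n_codes] <-
      rep_len(seq_len(config$n_groups), config$n_codes - idx + 1L)
  }
  names(group_of) <- codes

  n_excl <- round(config$attribute_exclusive_fraction * config$n_codes)
  allowed <- rep("both", config$n_codes)
  if (n_excl > 0) {
    # exclusive codes alternate levels and are spread across groups
    excl_idx <- unique(round(seq(1, config$n_codes, length.out = n_excl)))
    allowed[excl_idx] <- as.character(rep_len(0:1, length(excl_idx)))
  }
  names(allowed) <- codes
  list(group_of_code = group_of, allowed_attribute = allowed)
}
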