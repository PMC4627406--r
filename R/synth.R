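# Synthetic cohort generator.
#
# Emulates an emergency-triage cohort for pulmonary embolism work-up:
# continuous vitals and labs drawn from class-conditional normals placed
# so that the probability of crossing each variable's risk threshold
# shifts by a configurable log-odds between outcome classes; boolean
# symptoms/risk factors as class-conditional Bernoulli draws; and
# missing-not-at-random masking in which a value in the non-risk range
# is more likely to go unrecorded (clinicians chart abnormal findings
# more reliably than normal ones).

# Per-variable sampling model: distribution family, dispersion, recorded
# precision, and baseline probability of crossing into the risk ([1])
# range for an outcome-negative patient. Baselines reflect a pre-screened
# high-suspicion population, not the general public.
synth_variable_models <- function() {
  m <- function(name, family, p_base = NA, sd = NA, mean = NA, digits = 0) {
    data.frame(name = name, family = family, p_base = p_base,
               sd = sd, mean = mean, digits = digits)
  }
  rbind(
    m("Age",                  "threshold", p_base = 0.50, sd = 16),
    m("N_F_Pred",             "count",     p_base = 0.60),
    m("N_F_Risk",             "count",     p_base = 0.50),
    m("Previous DVT",         "boolean",   p_base = 0.20),
    m("Palpitations",         "boolean",   p_base = 0.25),
    m("Cough",                "boolean",   p_base = 0.30),
    m("dDimer",               "threshold", p_base = 0.60, sd = 300),
    m("PAS",                  "plain",     mean = 125,  sd = 25),
    m("PAD",                  "plain",     mean = 75,   sd = 15),
    m("FC",                   "threshold", p_base = 0.30, sd = 22),
    m("PAPS",                 "plain",     mean = 35,   sd = 15),
    m("WBC",                  "threshold", p_base = 0.30, sd = 3500),
    m("Cancer at diagnosis",  "boolean",   p_base = 0.15),
    m("Troponin",             "plain",     mean = 0.03, sd = 0.05, digits = 3),
    m("Shockindex",           "threshold", p_base = 0.25, sd = 0.18, digits = 2),
    m("Cancer",               "boolean",   p_base = 0.15),
    m("RVD",                  "boolean",   p_base = 0.20),
    m("Wells score",          "plain",     mean = 4,    sd = 2.5, digits = 1),
    m("Revised Geneva score", "plain",     mean = 8,    sd = 4),
    m("Wicki score",          "plain",     mean = 7,    sd = 3),
    m("Dyspnea",              "boolean",   p_base = 0.50),
    m("Chest pain",           "boolean",   p_base = 0.35),
    m("PCO2",                 "threshold", p_base = 0.20, sd = 8),
    m("PO2",                  "threshold", p_base = 0.60, sd = 12),
    m("PH",                   "threshold", p_base = 0.30, sd = 0.07, digits = 2),
    m("Hemoptysis",           "boolean",   p_base = 0.08)
  )
}

# Default per-variable missing-entry rates (fraction of patients with no
# recorded value), reproducing the observed non-uniform pattern of an
# emergency-department chart: echo-derived quantities mostly absent,
# vitals nearly complete.
default_missing_rates <- function() {
  c("Age" = 0.0007, "N_F_Pred" = 0.0664, "N_F_Risk" = 0.0755,
    "Previous DVT" = 0.3427, "Palpitations" = 0.1371, "Cough" = 0.1287,
    "dDimer" = 0.0776, "PAS" = 0.1133, "PAD" = 0.3818, "FC" = 0.0406,
    "PAPS" = 0.8580, "WBC" = 0.0266, "Cancer at diagnosis" = 0.4685,
    "Troponin" = 0.3993, "Shockindex" = 0.1189, "Cancer" = 0.4671,
    "RVD" = 0.6028, "Wells score" = 0.3580, "Revised Geneva score" = 0,
    "Wicki score" = 0.4650, "Dyspnea" = 0.1301, "Chest pain" = 0.1287,
    "PCO2" = 0.1692, "PO2" = 0.1664, "PH" = 0.4035, "Hemoptysis" = 0.3427)
}

# Default outcome effects, as log-odds shifts of crossing the risk
# threshold given a positive diagnosis; chosen on clinical grounds
# (d-Dimer the strongest single sign, then tachycardia, shock index,
# oxygenation, age and history).
default_effect_sizes <- function() {
  c("dDimer" = 1.5, "FC" = 1.0, "Shockindex" = 1.0, "PO2" = 0.8,
    "Age" = 0.7, "Previous DVT" = 0.7, "Dyspnea" = 0.8, "RVD" = 1.0,
    "Chest pain" = 0.4, "Palpitations" = 0.3, "Hemoptysis" = 0.5)
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients Number of patients (positive integer).
#' @param prevalence Fraction of positive final diagnoses in `[0,1]`;
#'   enforced as an exact rounded count, not by Bernoulli draws. The
#'   default mirrors a post-emergency-room cohort in which just over half
#'   the referred patients truly have the disease.
#' @param missing_rates Named vector, variable name -> missing fraction in
#'   `[0,1]`. Defaults to a realistic non-uniform chart pattern (about
#'   24 % of entries missing overall). Variables not named are never
#'   missing; `ID` and `Final diagnosis` are always complete.
#' @param effect_sizes Named vector, variable name -> log-odds shift of
#'   crossing that variable's risk threshold given a positive diagnosis.
#' @param mnar_boost Multiplicative factor >= 1 on a value's masking odds
#'   when the realized value lies in the non-risk (`[0]`) range; the
#'   per-variable base rate is renormalized so the marginal missing rate
#'   stays at `missing_rates`. `1` gives missing-completely-at-random.
#' @param seed Integer seed; generation is bit-reproducible for a fixed
#'   seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 1427, prevalence = 0.58,
                             missing_rates = default_missing_rates(),
                             effect_sizes = default_effect_sizes(),
                             mnar_boost = 1.5, seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 ||
      is.na(n_patients) || n_patients < 1 || n_patients != floor(n_patients))
    stop("invalid field 'n_patients': must be a positive integer")
  if (!is.numeric(prevalence) || length(prevalence) != 1 ||
      is.na(prevalence) || prevalence < 0 || prevalence > 1)
    stop("invalid field 'prevalence': must be in [0, 1]")
  if (length(missing_rates)) {
    if (is.null(names(missing_rates)) || any(names(missing_rates) == ""))
      stop("invalid field 'missing_rates': must be named by variable")
    if (any(is.na(missing_rates)) || any(missing_rates < 0) || any(missing_rates > 1))
      stop("invalid field 'missing_rates': rates must be in [0, 1]")
    unknown <- setdiff(names(missing_rates), cohort_schema()$name)
    if (length(unknown))
      stop("invalid field 'missing_rates': unknown variable(s) ",
           paste(unknown, collapse = ", "))
  }
  if (length(effect_sizes)) {
    if (is.null(names(effect_sizes)) || any(names(effect_sizes) == ""))
      stop("invalid field 'effect_sizes': must be named by variable")
    if (any(is.na(effect_sizes)))
      stop("invalid field 'effect_sizes': must be finite log-odds shifts")
    unknown <- setdiff(names(effect_sizes), cohort_schema()$name)
    if (length(unknown))
      stop("invalid field 'effect_sizes': unknown variable(s) ",
           paste(unknown, collapse = ", "))
  }
  if (!is.numeric(mnar_boost) || length(mnar_boost) != 1 ||
      is.na(mnar_boost) || mnar_boost < 1)
    stop("invalid field 'mnar_boost': must be a factor >= 1")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed != floor(seed))
    stop("invalid field 'seed': must be an integer")
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 missing_rates = missing_rates, effect_sizes = effect_sizes,
                 mnar_boost = mnar_boost, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic cohort config:", x$n_patients, "patients,",
      sprintf("prevalence %.2f,", x$prevalence),
      length(x$effect_sizes), "effect variables,",
      sprintf("mnar_boost %.2f, seed %d\n", x$mnar_boost, x$seed))
  invisible(x)
}

# Run code under a private RNG stream without disturbing the caller's.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic cohort
#'
#' Produces a full 28-column cohort table. Labels are assigned first
#' (exact rounded positive count), values are drawn conditionally on the
#' label, and missingness is applied last by masking realized values, so
#' the mechanism is missing-not-at-random whenever `mnar_boost > 1`.
#'
#' For a threshold variable with risk cut `t` and baseline crossing
#' probability `p0`, the class-conditional normal mean is placed at
#' `t - sd * qnorm(1 - p)` with `p = plogis(qlogis(p0) + effect)` for
#' positives, so the configured log-odds shift is realized at the cut.
#'
#' @param config A [synthetic_config()].
#' @return Cohort data frame with the 28 schema columns; missing entries
#'   are `NA` in memory and the literal `NaN` on disk
#'   (see [write_cohort_csv()]).
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_patients = 100, seed = 1))
#' sum(cohort[["Final diagnosis"]])  # exact prevalence: 58 positives
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, as.list(config))
  n <- config$n_patients
  models <- synth_variable_models()
  map <- default_threshold_map()
  with_seed(config$seed, {
    labels <- integer(n)
    n_pos <- round(n * config$prevalence)
    labels[sample.int(n, n_pos)] <- 1L
    cohort <- data.frame(ID = sprintf("P%05d", seq_len(n)),
                         check.names = FALSE, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(models))) {
      v <- models$name[i]
      eff <- if (v %in% names(config$effect_sizes)) config$effect_sizes[[v]] else 0
      p_class <- stats::plogis(stats::qlogis(models$p_base[i]) + eff * labels)
      x <- switch(models$family[i],
        boolean = as.numeric(stats::runif(n) < p_class),
        count = stats::rpois(n, -log(1 - p_class)),
        threshold = {
          j <- match(v, map$variable)
          t_cut <- map$pos_min[j]
          mu <- t_cut - models$sd[i] * stats::qnorm(1 - p_class)
          round(stats::rnorm(n, mu, models$sd[i]), models$digits[i])
        },
        plain = round(stats::rnorm(n, models$mean[i], models$sd[i]),
                      models$digits[i])
      )
      if (v %in% c("Troponin", "Wicki score", "Wells score")) x <- pmax(x, 0)
      # MNAR masking: values in the non-risk range are boost times as
      # likely to be unrecorded; base rate renormalized so the marginal
      # missing rate matches the configured one.
      rate <- if (v %in% names(config$missing_rates)) config$missing_rates[[v]] else 0
      if (rate > 0) {
        in_anti <- if (v %in% map$variable) {
          j <- match(v, map$variable)
          range_hit(x, map$anti_min[j], map$anti_min_open[j],
                    map$anti_max[j], map$anti_max_open[j])
        } else rep(FALSE, n)
        w <- ifelse(in_anti, config$mnar_boost, 1)
        p_miss <- pmin(rate * w / mean(w), 1)
        x[stats::runif(n) < p_miss] <- NA
      }
      cohort[[v]] <- x
    }
    cohort[["Final diagnosis"]] <- labels
    cohort
  })
}
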