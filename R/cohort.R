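#' Synthetic cohort configuration
#'
#' Parameters of the synthetic relapse-cohort generator. The generator
#' emulates the structure of a clinical AML relapse cohort: per patient a
#' generating model variant is drawn, leukemic parameters are drawn from
#' priors over the fitting box, the remission-to-relapse blast trajectory
#' is simulated, sparse irregular marrow examinations are sampled
#' (routine checks every 30-90 days, denser once blasts are detectable),
#' truncated-Gaussian measurement noise is added, values below the
#' reporting threshold become interval records ("less than 5% blasts"),
#' and an overall-survival time is drawn from a group-specific exponential
#' with administrative censoring.
#'
#' Default priors: cytokine-independent patients draw self-renewal from
#' `U(0.75, 1)` and proliferation log-uniformly from `[0.25, 1]`/day,
#' giving the fast relapses characteristic of autonomous growth;
#' cytokine-dependent patients draw self-renewal from `U(a_c + 0.01, 1)`
#' (expansion requires exceeding the healthy self-renewal) and
#' proliferation log-uniformly from `[0.2, 1]`/day. Draws whose relapse
#' (blast fraction reaching `relapse_level`) falls outside the observation
#' horizon are redrawn.
#'
#' @param n_patients cohort size (default 41).
#' @param fraction_model2 probability that a patient's leukemia is
#'   cytokine-independent (default 17/41).
#' @param noise_sd blast-fraction measurement noise (default 0.02).
#' @param reporting_threshold fraction below which a measurement is
#'   reported as an interval "less than" record (default 0.05).
#' @param relapse_level blast fraction at which relapse is documented and
#'   observation ends (default 0.25).
#' @param horizon maximum days from remission to documented relapse;
#'   slower draws are rejected (default 1200).
#' @param os_median_model1,os_median_model2 median overall survival (days)
#'   of the exponential survival generator per generating model
#'   (defaults 700 and 350).
#' @param censoring_fraction expected fraction of censored survival times
#'   (default 0.1; relapse cohorts with documented outcomes have few
#'   censored patients). Censoring is independent exponential, calibrated
#'   so its expected share equals this value.
#' @param l0_range range (cells/kg) of the residual leukemic burden at
#'   remission, drawn log-uniformly.
#' @param healthy,k,dbar shared model parameters.
#' @param seed RNG seed; the whole cohort is deterministic given the seed.
#' @return A list of class `leukdyn_cohort_config`.
#' @export
cohort_config <- function(n_patients = 41L,
                          fraction_model2 = 17 / 41,
                          noise_sd = 0.02,
                          reporting_threshold = 0.05,
                          relapse_level = 0.25,
                          horizon = 1200,
                          os_median_model1 = 700,
                          os_median_model2 = 350,
                          censoring_fraction = 0.1,
                          l0_range = c(10, 1e4),
                          healthy = default_healthy_params(),
                          k = 1e-9, dbar = 1e-12,
                          seed = 1L) {
  stopifnot(n_patients >= 1L,
            fraction_model2 >= 0, fraction_model2 <= 1,
            noise_sd >= 0, reporting_threshold >= 0, reporting_threshold < 1,
            relapse_level > reporting_threshold, relapse_level < 1,
            os_median_model1 > 0, os_median_model2 > 0,
            censoring_fraction >= 0, censoring_fraction < 1)
  structure(list(n_patients = as.integer(n_patients),
                 fraction_model2 = fraction_model2,
                 noise_sd = noise_sd,
                 reporting_threshold = reporting_threshold,
                 relapse_level = relapse_level,
                 horizon = horizon,
                 os_median_model1 = os_median_model1,
                 os_median_model2 = os_median_model2,
                 censoring_fraction = censoring_fraction,
                 l0_range = l0_range,
                 healthy = healthy, k = k, dbar = dbar,
                 seed = as.integer(seed)),
            class = "leukdyn_cohort_config")
}

## one truncated-Gaussian noise draw on [0, 1]
.trunc_noise <- function(mean, sd) {
  if (sd == 0) return(min(max(mean, 0), 1))
  for (i in 1:100) {
    x <- rnorm(1L, mean, sd)
    if (x >= 0 && x <= 1) return(x)
  }
  min(max(mean, 0), 1)
}

## draw leukemic parameters for one patient of the given variant
.draw_leukemic <- function(variant, cfg) {
  hc <- cfg$healthy
  if (variant == "model2") {
    a <- runif(1L, 0.75, 1)
    p <- exp(runif(1L, log(0.25), log(1)))
  } else {
    a <- runif(1L, min(hc$a + 0.01, 0.999), 1)
    p <- exp(runif(1L, log(0.2), log(1)))
  }
  d <- runif(1L, hc$d, 4 * hc$d)
  lineage_params(a, p, d)
}

#' Generate a synthetic relapse cohort
#'
#' See [cohort_config()] for the generating process. Each record carries
#' the generating truth alongside the observables so that downstream
#' model-recovery experiments can be scored.
#'
#' @param config a [cohort_config()].
#' @param max_retries redraw attempts per patient before giving up
#'   (default 200).
#' @return A `leukdyn_cohort`: list of records, each with `patient_id`,
#'   `true_variant`, `true_params`, `l0`, `t_relapse` (days from remission
#'   to the documented-relapse level), `t_to_10pct` (days to a 10% blast
#'   fraction), `observations` (an [observation_table()]), `os_days` and
#'   `event`.
#' @export
generate_cohort <- function(config, max_retries = 200L) {
  stopifnot(inherits(config, "leukdyn_cohort_config"))
  cfg <- config
  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed), add = TRUE)
  set.seed(cfg$seed)

  records <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    variant <- if (runif(1L) < cfg$fraction_model2) "model2" else "model1"
    rec <- NULL
    for (try in seq_len(max_retries)) {
      lc <- .draw_leukemic(variant, cfg)
      l0 <- exp(runif(1L, log(cfg$l0_range[1]), log(cfg$l0_range[2])))
      pars <- model_params(lc, healthy = cfg$healthy, k = cfg$k,
                           dbar = cfg$dbar, variant = variant)
      eq <- healthy_equilibrium(pars)
      init <- eq
      init["l1"] <- init["l1"] + l0
      t_rel <- time_to_blast_threshold(pars, threshold = cfg$relapse_level,
                                       horizon = cfg$horizon, init = init)
      if (!is.finite(t_rel)) next
      t_10 <- time_to_blast_threshold(pars, threshold = 0.10,
                                      horizon = cfg$horizon, init = init)
      ## dense trajectory for scheduling and measurement
      traj <- simulate_model(pars, init = init, t_end = t_rel,
                             times = sort(unique(c(seq(0, t_rel, by = 1), t_rel))))
      bf_at <- function(tt) approx(traj$t, traj$blast_fraction, xout = tt,
                                   rule = 2)$y
      ## routine checks every 30-90 days; every 10-21 days once blasts
      ## are clearly detectable; final examination documents the relapse
      tt <- 0
      sched <- 0
      repeat {
        step <- if (bf_at(tt) < 0.10) runif(1L, 30, 90) else runif(1L, 10, 21)
        tt <- tt + step
        if (tt >= t_rel) break
        sched <- c(sched, tt)
      }
      sched <- c(sched, t_rel)
      bf_true <- bf_at(sched)
      bf_meas <- vapply(bf_true, .trunc_noise, numeric(1), sd = cfg$noise_sd)
      is_iv <- bf_meas < cfg$reporting_threshold
      obs <- observation_table(
        t = sched,
        kind = ifelse(is_iv, "interval", "exact"),
        value = ifelse(is_iv, NA_real_, bf_meas),
        lower = ifelse(is_iv, 0, NA_real_),
        upper = ifelse(is_iv, cfg$reporting_threshold, NA_real_),
        patient_id = sprintf("P%03d", i))
      med <- if (variant == "model2") cfg$os_median_model2 else cfg$os_median_model1
      rate <- log(2) / med
      os <- rexp(1L, rate)
      event <- 1L
      if (cfg$censoring_fraction > 0) {
        ## independent exponential censoring calibrated so that the
        ## expected censored fraction equals the configured one
        cens <- rexp(1L, rate * cfg$censoring_fraction /
                           (1 - cfg$censoring_fraction))
        if (cens < os) {
          os <- cens
          event <- 0L
        }
      }
      os <- max(os, 1)
      rec <- list(patient_id = sprintf("P%03d", i),
                  true_variant = variant, true_params = pars, l0 = l0,
                  t_relapse = t_rel, t_to_10pct = t_10,
                  observations = obs, os_days = os, event = event,
                  retries = try - 1L)
      break
    }
    if (is.null(rec))
      stop(sprintf("patient %d: no relapsing parameter draw within %d retries",
                   i, max_retries))
    records[[i]] <- rec
  }
  structure(records, config = cfg, class = "leukdyn_cohort")
}

#' @export
print.leukdyn_cohort <- function(x, ...) {
  v <- vapply(x, `[[`, character(1), "true_variant")
  cat(sprintf("synthetic cohort: %d patients (%d cytokine-dependent, %d cytokine-independent)\n",
              length(x), sum(v == "model1"), sum(v == "model2")))
  invisible(x)
}

#' Cohort truth and survival tables
#'
#' @param x a `leukdyn_cohort`.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return `as.data.frame()`: the truth sidecar, one row per patient with
#'   generating variant, parameters, relapse times and survival outcome.
#' @export
as.data.frame.leukdyn_cohort <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  do.call(rbind, lapply(x, function(r) {
    lc <- r$true_params$leukemic
    data.frame(patient_id = r$patient_id, true_variant = r$true_variant,
               a_l = lc$a, p_l = lc$p, d_l = lc$d, l0 = r$l0,
               t_relapse = r$t_relapse, t_to_10pct = r$t_to_10pct,
               os_days = r$os_days, event = r$event)
  }))
}

#' Write a cohort to CSV files
#'
#' Emits `observations.csv` (the [read_observations()] dialect),
#' `truth.csv` (generating variant and parameters) and `survival.csv`
#' (`patient_id`, `os_days`, `event`) into `dir`.
#'
#' @param cohort a `leukdyn_cohort`.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "leukdyn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obs_list <- lapply(cohort, `[[`, "observations")
  names(obs_list) <- vapply(cohort, `[[`, character(1), "patient_id")
  write_observations(obs_list, file.path(dir, "observations.csv"))
  truth <- as.data.frame(cohort)
  write.csv(truth[, c("patient_id", "true_variant", "a_l", "p_l", "d_l",
                      "l0", "t_relapse", "t_to_10pct")],
            file.path(dir, "truth.csv"), row.names = FALSE)
  write.csv(truth[, c("patient_id", "os_days", "event")],
            file.path(dir, "survival.csv"), row.names = FALSE)
  invisible(dir)
}
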