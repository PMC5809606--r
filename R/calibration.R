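#' Patient blast observation table
#'
#' A patient's marrow blast measurements over time, as fractions. Each
#' observation is either `"exact"` (a reported blast fraction) or
#' `"interval"` (a reported range such as "less than 5% blasts", encoded
#' by `lower`/`upper` bounds).
#'
#' @param t observation times in days since first remission; strictly
#'   increasing, at least two.
#' @param kind character vector, `"exact"` or `"interval"` per observation.
#' @param value blast fraction for exact observations (`NA` otherwise).
#' @param lower,upper interval bounds for interval observations
#'   (`NA` otherwise).
#' @param patient_id optional identifier.
#' @return A data frame of class `leukdyn_obs` with columns `t`, `kind`,
#'   `value`, `lower`, `upper`.
#' @examples
#' observation_table(t = c(0, 120, 180),
#'                   kind = c("interval", "exact", "exact"),
#'                   value = c(NA, 0.08, 0.22),
#'                   lower = c(0, NA, NA), upper = c(0.05, NA, NA))
#' @export
observation_table <- function(t, kind, value = NA_real_,
                              lower = NA_real_, upper = NA_real_,
                              patient_id = NA_character_) {
  n <- length(t)
  if (n < 2L) stop("an observation table needs at least two observations")
  if (is.unsorted(t, strictly = TRUE))
    stop("observation times must be strictly increasing")
  kind <- match.arg(kind, c("exact", "interval"), several.ok = TRUE)
  kind <- rep_len(kind, n)
  value <- rep_len(value, n); lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  ex <- kind == "exact"
  if (any(ex & (!is.finite(value) | value < 0 | value > 1)))
    stop("exact observations need a blast fraction value in [0, 1]")
  iv <- !ex
  if (any(iv & (!is.finite(lower) | !is.finite(upper) | lower > upper |
                  lower < 0 | upper > 1)))
    stop("interval observations need bounds 0 <= lower <= upper <= 1")
  structure(data.frame(t = t, kind = kind, value = value,
                       lower = lower, upper = upper),
            patient_id = patient_id,
            class = c("leukdyn_obs", "data.frame"))
}

#' Read/write observation tables as CSV
#'
#' The CSV dialect carries blast values as percentages: columns
#' `patient_id`, `t_days`, `blast_pct_exact` (empty for interval records),
#' `blast_pct_lower`, `blast_pct_upper`. Percentages are converted to
#' fractions on load.
#'
#' @param path CSV file.
#' @return `read_observations()`: a named list of [observation_table()]
#'   objects, one per patient.
#' @export
read_observations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "t_days", "blast_pct_exact",
            "blast_pct_lower", "blast_pct_upper")
  if (!all(need %in% names(df)))
    stop("observation CSV must have columns: ", paste(need, collapse = ", "))
  split_df <- split(df, df$patient_id)
  lapply(split_df, function(d) {
    d <- d[order(d$t_days), ]
    ex <- !is.na(d$blast_pct_exact)
    observation_table(t = d$t_days,
                      kind = ifelse(ex, "exact", "interval"),
                      value = d$blast_pct_exact / 100,
                      lower = d$blast_pct_lower / 100,
                      upper = d$blast_pct_upper / 100,
                      patient_id = as.character(d$patient_id[1L]))
  })
}

#' @rdname read_observations
#' @param obs_list named list of `leukdyn_obs` tables.
#' @export
write_observations <- function(obs_list, path) {
  rows <- lapply(obs_list, function(o) {
    data.frame(patient_id = attr(o, "patient_id"),
               t_days = o$t,
               blast_pct_exact = ifelse(o$kind == "exact", 100 * o$value, NA),
               blast_pct_lower = ifelse(o$kind == "interval", 100 * o$lower, NA),
               blast_pct_upper = ifelse(o$kind == "interval", 100 * o$upper, NA))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Biologically plausible fitting bounds
#'
#' Patient-specific leukemic parameters are restricted to: proliferation
#' rate between one division per two years and one division per day;
#' self-renewal between zero and one; post-mitotic death rate between the
#' healthy leukocyte rate and four times that rate (blast half-life
#' between 25% and 100% of the leukocyte half-life, since rate =
#' ln 2 / half-life); and a residual leukemic burden at remission between
#' `1e-2` and `1e6` cells/kg, searched on a log scale.
#'
#' @param healthy healthy-lineage parameters (sets the `d_l` range).
#' @return A list of `c(lower, upper)` pairs for `a_l`, `p_l`, `d_l`, `l0`.
#' @export
fit_bounds <- function(healthy = default_healthy_params()) {
  list(a_l = c(0, 1),
       p_l = c(1 / 730, 1),
       d_l = c(healthy$d, 4 * healthy$d),
       l0 = c(1e-2, 1e6))
}

## residual vector of one parameter point against the observations:
## exact -> model - value; interval -> distance to the interval (0 inside)
.fit_residuals <- function(a_l, p_l, d_l, l0, variant, obs, healthy, k, dbar,
                           eq = NULL) {
  pars <- model_params(lineage_params(a_l, p_l, d_l), healthy = healthy,
                       k = k, dbar = dbar, variant = variant)
  if (is.null(eq)) eq <- healthy_equilibrium(pars)
  init <- eq
  init["l1"] <- init["l1"] + l0
  times <- sort(unique(c(0, obs$t)))
  m <- tryCatch(
    .integrate_segment(pars, init, times = times),
    error = function(e) NULL)
  if (is.null(m)) return(rep(1e3, nrow(obs)))
  bf <- m[, "l1"] / (m[, "c1"] + m[, "l1"])
  bf_obs <- bf[match(obs$t, m[, 1L])]
  ifelse(obs$kind == "exact",
         bf_obs - obs$value,
         pmax(0, obs$lower - bf_obs, bf_obs - obs$upper))
}

#' Least-squares objective: RMSE of a model against blast observations
#'
#' Simulates the model from the remission initial condition (healthy
#' compartments at equilibrium, residual leukemic mitotic burden `l0`)
#' and evaluates the marrow blast fraction at the observation times. The
#' residual of an exact observation is `model - value`; the residual of an
#' interval observation is its distance to the interval (zero inside).
#' Returns the root mean square of the residuals, in blast-fraction units.
#'
#' @param leukemic a [lineage_params()] object for the leukemic lineage.
#' @param l0 residual leukemic mitotic density at remission (cells/kg).
#' @param variant `"model1"` or `"model2"`.
#' @param obs an [observation_table()].
#' @param healthy,k,dbar shared model parameters.
#' @return RMSE (`>= 0`); failed integrations yield a large penalty value.
#' @export
objective_rmse <- function(leukemic, l0, variant, obs,
                           healthy = default_healthy_params(),
                           k = 1e-9, dbar = 1e-12) {
  stopifnot(inherits(obs, "leukdyn_obs"), inherits(leukemic, "leukdyn_lineage"))
  r <- .fit_residuals(leukemic$a, leukemic$p, leukemic$d, l0,
                      variant, obs, healthy, k, dbar)
  sqrt(mean(r^2))
}

#' Fit one model variant to a patient's blast time course
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) from `n_starts`
#' Latin-hypercube initializations over the box of [fit_bounds()];
#' proliferation rate and remission burden are searched on a log scale.
#' The best converged start is returned. Deterministic given `seed`.
#'
#' @param variant `"model1"` or `"model2"`.
#' @param obs an [observation_table()].
#' @param bounds parameter box, see [fit_bounds()].
#' @param n_starts number of multistart initializations (default 32).
#' @param seed RNG seed for the start design.
#' @param healthy,k,dbar shared model parameters.
#' @param maxiter per-start Levenberg-Marquardt iteration cap.
#' @return A `leukdyn_fit` list: `variant`, `params` (best-fit
#'   [model_params()]), `l0`, `rmse`, `n_obs`, `converged`, and a
#'   `multistart` data frame logging every start.
#' @export
fit_model <- function(variant = c("model1", "model2"), obs,
                      bounds = NULL, n_starts = 32L, seed = 1L,
                      healthy = default_healthy_params(),
                      k = 1e-9, dbar = 1e-12, maxiter = 60L) {
  variant <- match.arg(variant)
  stopifnot(inherits(obs, "leukdyn_obs"), n_starts >= 1L)
  if (is.null(bounds)) bounds <- fit_bounds(healthy)

  ## transformed coordinates: a_l raw, log10 p_l, d_l raw, log10 l0
  lower <- c(bounds$a_l[1], log10(bounds$p_l[1]), bounds$d_l[1],
             log10(bounds$l0[1]))
  upper <- c(bounds$a_l[2], log10(bounds$p_l[2]), bounds$d_l[2],
             log10(bounds$l0[2]))
  ## the healthy equilibrium does not depend on the fitted parameters
  eq <- healthy_equilibrium(model_params(lineage_params(0.5, 0.5, healthy$d),
                                         healthy = healthy, k = k,
                                         dbar = dbar, variant = variant))
  resid_fn <- function(theta) {
    .fit_residuals(theta[1], 10^theta[2], theta[3], 10^theta[4],
                   variant, obs, healthy, k, dbar, eq = eq)
  }
  ## least-squares routines need at least as many residuals as parameters;
  ## pad very sparse tables with zero residuals (the RMSE is recomputed
  ## from the true residuals afterwards)
  n_res <- nrow(obs)
  fn_padded <- function(theta) {
    r <- resid_fn(theta)
    if (length(r) < 4L) r <- c(r, rep(0, 4L - length(r)))
    r
  }

  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed), add = TRUE)
  set.seed(seed)
  design <- lhs::randomLHS(n_starts, 4L)
  starts <- sweep(sweep(design, 2L, upper - lower, "*"), 2L, lower, "+")
  ## a leukemic clone can only expand when a_l * s exceeds 1/2, i.e. above
  ## the healthy self-renewal under the cytokine-dependent model and above
  ## 1/2 under the autonomous one; place half of the starts there so the
  ## optimizer always explores the relapse-capable region
  grow_lower <- max(bounds$a_l[1],
                    if (variant == "model1") min(healthy$a, 0.99) else 0.5)
  idx <- seq_len(ceiling(n_starts / 2))
  starts[idx, 1L] <- grow_lower +
    (starts[idx, 1L] - lower[1]) / (upper[1] - lower[1]) *
      (bounds$a_l[2] - grow_lower)

  log <- vector("list", n_starts)
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                           fn = fn_padded,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter, ptol = 1e-10, ftol = 1e-10))),
      error = function(e) NULL)
    if (is.null(fit)) {
      log[[i]] <- data.frame(start = i, rmse = NA_real_, converged = FALSE)
      next
    }
    rmse <- sqrt(mean(fit$fvec[seq_len(n_res)]^2))
    ## iteration-capped runs (info 5 / -1) still carry their best point
    ok <- fit$info %in% c(1:5, -1L)
    log[[i]] <- data.frame(start = i, rmse = rmse, converged = ok)
    if (ok && (is.null(best) || rmse < best$rmse))
      best <- list(par = fit$par, rmse = rmse)
  }
  multistart <- do.call(rbind, log)

  if (is.null(best)) {
    return(structure(list(variant = variant, params = NULL, l0 = NA_real_,
                          rmse = NA_real_, n_obs = nrow(obs),
                          converged = FALSE, multistart = multistart),
                     class = "leukdyn_fit"))
  }
  th <- best$par
  params <- model_params(lineage_params(th[1], 10^th[2], th[3]),
                         healthy = healthy, k = k, dbar = dbar,
                         variant = variant)
  structure(list(variant = variant, params = params, l0 = 10^th[4],
                 rmse = best$rmse, n_obs = nrow(obs), converged = TRUE,
                 multistart = multistart),
            class = "leukdyn_fit")
}

#' @export
print.leukdyn_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("fit (%s): did not converge (%d observations)\n",
                x$variant, x$n_obs))
    return(invisible(x))
  }
  lc <- x$params$leukemic
  cat(sprintf("fit (%s): rmse = %.4g on %d observations\n",
              x$variant, x$rmse, x$n_obs))
  cat(sprintf("  a_l = %.4g, p_l = %.4g /day, d_l = %.4g /day, l0 = %.3g cells/kg\n",
              lc$a, lc$p, lc$d, x$l0))
  invisible(x)
}

#' Model selection by the relative-RMSE rule
#'
#' A model is deemed the better fit when the competing model's RMSE
#' exceeds it by more than `tol` (default 5%): the cytokine-independent
#' model is preferred iff `rmse1 > (1 + tol) * rmse2` and vice versa;
#' otherwise both models are compatible with the data. Patients whose data
#' are compatible with the cytokine-dependent model (alone or together
#' with the other model) form `"group1"`; patients compatible only with
#' the cytokine-independent model form `"group2"`.
#'
#' Before the relative comparison both RMSEs are floored at `floor`
#' (default 0.005, half a blast percentage point): marrow blast counts are
#' not reported below roughly percent resolution, so ratios of RMSEs that
#' are both below measurement resolution carry no information and such
#' fits are treated as equally good.
#'
#' @param fit1 `leukdyn_fit` of the cytokine-dependent model (`"model1"`).
#' @param fit2 `leukdyn_fit` of the cytokine-independent model (`"model2"`).
#' @param tol relative RMSE margin (default 0.05).
#' @param floor RMSE resolution floor in blast-fraction units (default
#'   0.005).
#' @return A list: `compatible` (named logical for each model),
#'   `preferred` (`"model1"`, `"model2"` or `"both"`), and `group`
#'   (`"group1"`, `"group2"`, or `"undetermined"` when either fit failed).
#' @examples
#' f1 <- structure(list(variant = "model1", rmse = 0.106, converged = TRUE),
#'                 class = "leukdyn_fit")
#' f2 <- structure(list(variant = "model2", rmse = 0.100, converged = TRUE),
#'                 class = "leukdyn_fit")
#' select_model(f1, f2)$group  # "group2": model 1 misses by more than 5%
#' @export
select_model <- function(fit1, fit2, tol = 0.05, floor = 0.005) {
  stopifnot(inherits(fit1, "leukdyn_fit"), inherits(fit2, "leukdyn_fit"))
  if (!isTRUE(fit1$converged) || !isTRUE(fit2$converged)) {
    return(list(compatible = c(model1 = NA, model2 = NA),
                preferred = NA_character_, group = "undetermined"))
  }
  r1 <- max(fit1$rmse, floor)
  r2 <- max(fit2$rmse, floor)
  prefer2 <- r1 > (1 + tol) * r2
  prefer1 <- r2 > (1 + tol) * r1
  compatible <- c(model1 = !prefer2, model2 = !prefer1)
  preferred <- if (prefer2) "model2" else if (prefer1) "model1" else "both"
  group <- if (prefer2) "group2" else "group1"
  list(compatible = compatible, preferred = preferred, group = group)
}

## save/restore the global RNG state so seeded internals do not disturb
## the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}
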