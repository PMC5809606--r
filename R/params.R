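#' Cell-lineage parameters
#'
#' Bundles the three kinetic parameters of one lineage (healthy or
#' leukemic): the fraction of self-renewal `a`, the proliferation rate `p`
#' and the post-mitotic death rate `d`. Mitotic cells do not die under
#' physiological conditions; their only loss term is density-dependent
#' crowding death (see [model_params()]).
#'
#' @param a fraction of self-renewal, the probability that a progeny cell
#'   adopts the fate of its parent; dimensionless, in `[0, 1]`.
#' @param p proliferation rate in divisions per day; `>= 0`.
#' @param d post-mitotic death rate in 1/day; `> 0`.
#' @return A list of class `leukdyn_lineage`.
#' @examples
#' lineage_params(a = 0.8, p = 0.5, d = 2.3)
#' @export
lineage_params <- function(a, p, d) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(p), length(p) == 1L, is.finite(p),
            is.numeric(d), length(d) == 1L, is.finite(d))
  if (a < 0 || a > 1) stop("fraction of self-renewal `a` must lie in [0, 1]")
  if (p < 0) stop("proliferation rate `p` must be >= 0")
  if (d <= 0) stop("post-mitotic death rate `d` must be > 0")
  structure(list(a = a, p = p, d = d), class = "leukdyn_lineage")
}

#' Default healthy-lineage parameters
#'
#' Healthy granulopoiesis parameters shared by all simulations and fits:
#' self-renewal fraction 0.93, proliferation rate 0.7 divisions/day (the
#' mitotic pool is dominated by rapidly dividing progenitors), and a
#' post-mitotic death rate of 2.3/day (leukocyte half-life of about seven
#' hours). Together with the default feedback strength they place the
#' mature-cell equilibrium near 8.6e8 cells/kg and calibrate the model so
#' that cytokine-dependent leukemic expansion from a single leukemic stem
#' cell per kg needs at least roughly 200 days to reach a 10% marrow blast
#' fraction, while cytokine-independent expansion can do so within a month.
#'
#' @return A `leukdyn_lineage` object.
#' @export
default_healthy_params <- function() {
  lineage_params(a = 0.93, p = 0.7, d = 2.3)
}

#' Full model parameter set
#'
#' Combines healthy and leukemic lineage parameters with the two coupling
#' parameters and the model-variant tag. `k` is the strength of the
#' cytokine feedback `s = 1/(1 + k * C)`, where the consumer pool `C` is
#' the mature healthy plus mature leukemic cells under `"model1"`
#' (cytokine-dependent AML; leukemic cells compete for the cytokine) and
#' the mature healthy cells alone under `"model2"` (cytokine-independent
#' AML). `dbar` scales the crowding death rate `dbar * (c1 + l1)` that acts
#' on both mitotic compartments; it is negligible at healthy homeostasis
#' and caps autonomous leukemic expansion.
#'
#' @param leukemic,healthy [lineage_params()] objects.
#' @param k feedback strength in 1/(cells/kg); `> 0`.
#' @param dbar crowding death coefficient in 1/((cells/kg) * day); `>= 0`.
#' @param variant `"model1"` (cytokine-dependent leukemia) or `"model2"`
#'   (cytokine-independent leukemia).
#' @return A list of class `leukdyn_params`.
#' @examples
#' model_params(lineage_params(0.99, 0.6, 2.3), variant = "model2")
#' @export
model_params <- function(leukemic,
                         healthy = default_healthy_params(),
                         k = 1e-9,
                         dbar = 1e-12,
                         variant = c("model1", "model2")) {
  variant <- match.arg(variant)
  stopifnot(inherits(leukemic, "leukdyn_lineage"),
            inherits(healthy, "leukdyn_lineage"))
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("feedback strength `k` must be a single positive number")
  if (!is.numeric(dbar) || length(dbar) != 1L || !is.finite(dbar) || dbar < 0)
    stop("crowding coefficient `dbar` must be a single non-negative number")
  if (healthy$a <= 0.5)
    stop("healthy self-renewal must exceed 0.5 for a positive equilibrium")
  structure(list(healthy = healthy, leukemic = leukemic,
                 k = k, dbar = dbar, variant = variant),
            class = "leukdyn_params")
}

#' @export
print.leukdyn_lineage <- function(x, ...) {
  cat(sprintf("lineage: a = %.4g, p = %.4g /day, d = %.4g /day\n",
              x$a, x$p, x$d))
  invisible(x)
}

#' @export
print.leukdyn_params <- function(x, ...) {
  lab <- if (x$variant == "model1") "cytokine-dependent (model1)"
         else "cytokine-independent (model2)"
  cat("AML competition model:", lab, "\n")
  cat(sprintf("  healthy : a = %.4g, p = %.4g, d = %.4g\n",
              x$healthy$a, x$healthy$p, x$healthy$d))
  cat(sprintf("  leukemic: a = %.4g, p = %.4g, d = %.4g\n",
              x$leukemic$a, x$leukemic$p, x$leukemic$d))
  cat(sprintf("  k = %.3g /(cells/kg), dbar = %.3g /((cells/kg) day)\n",
              x$k, x$dbar))
  invisible(x)
}

#' Cytokine stimulation protocol
#'
#' Describes a window of exogenous cytokine administration ("priming").
#' During the window the feedback signal experienced by cytokine-responsive
#' compartments is clamped to its maximum `s = 1`: both lineages respond
#' under `"model1"`, only the healthy lineage under `"model2"` (leukemic
#' cells there are signal-independent throughout).
#'
#' @param t_start day the stimulation begins.
#' @param duration length of the window in days (default 30).
#' @return A list of class `leukdyn_protocol`.
#' @export
stimulation_protocol <- function(t_start, duration = 30) {
  stopifnot(is.numeric(t_start), length(t_start) == 1L, is.finite(t_start),
            t_start >= 0)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("stimulation `duration` must be > 0")
  structure(list(t_start = t_start, duration = duration,
                 mode = "clamp_signal_max"),
            class = "leukdyn_protocol")
}

## parameter vector in the order expected by the compiled derivatives
.parm_vector <- function(params, stimulated = FALSE, thr = 0, trigger = 0) {
  c(a_c = params$healthy$a, p_c = params$healthy$p, d_c = params$healthy$d,
    a_l = params$leukemic$a, p_l = params$leukemic$p, d_l = params$leukemic$d,
    k = params$k, dbar = params$dbar,
    mod2 = as.numeric(params$variant == "model2"),
    stim = as.numeric(stimulated),
    thr = thr, trigger = trigger)
}
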