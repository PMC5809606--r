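#' Cytokine feedback signal
#'
#' The endogenous cytokine signal perceived by mitotic compartments,
#' `s = 1/(1 + k * C)`, where `C` is the density of mature cells consuming
#' the cytokine by receptor-mediated endocytosis. `s` is maximal (1) when
#' no consumers are present and decreases strictly with `C`. Under
#' exogenous stimulation the signal is clamped to its maximum.
#'
#' @param k feedback strength in 1/(cells/kg); `> 0`.
#' @param consuming_mature density `C` of cytokine-consuming mature cells
#'   (cells/kg); `>= 0`. Vectorized.
#' @param stimulated if `TRUE` the signal is clamped to 1.
#' @return Signal value(s) in `(0, 1]`.
#' @examples
#' feedback_signal(1e-9, 0)        # 1: no consumers
#' feedback_signal(2e-9, 1e9)      # 1/3
#' @export
feedback_signal <- function(k, consuming_mature, stimulated = FALSE) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("feedback strength `k` must be a single positive number")
  if (any(!is.finite(consuming_mature)) || any(consuming_mature < 0))
    stop("consumer density must be finite and >= 0")
  if (isTRUE(stimulated)) rep(1, length(consuming_mature))
  else 1 / (1 + k * consuming_mature)
}

#' Effective growth rate of a mitotic compartment
#'
#' Net per-capita production rate `(2 * a * s - 1) * p` of a mitotic cell
#' population with self-renewal fraction `a`, proliferation rate `p` and
#' signal `s`: each division produces two progeny of which a fraction
#' `a * s` self-renews. A compartment expands iff its effective growth
#' rate is positive, i.e. iff `a * s > 1/2`; a high proliferation rate
#' with modest self-renewal can match the rate of slow proliferation with
#' high self-renewal. For cytokine-independent leukemic cells `s` is
#' identically 1.
#'
#' @param a fraction of self-renewal in `[0, 1]`.
#' @param p proliferation rate (divisions/day), `>= 0`.
#' @param s signal in `[0, 1]` (default 1).
#' @return Effective growth rate in 1/day. Vectorized over its arguments.
#' @examples
#' effective_growth_rate(0.5, 1)            # 0: neutral
#' effective_growth_rate(0.9, 0.2)          # 0.16
#' effective_growth_rate(0.58, 1.0)         # 0.16: same rate, other trade-off
#' @export
effective_growth_rate <- function(a, p, s = 1) {
  if (any(a < 0 | a > 1)) stop("self-renewal `a` must lie in [0, 1]")
  if (any(p < 0)) stop("proliferation rate `p` must be >= 0")
  if (any(s < 0 | s > 1)) stop("signal `s` must lie in [0, 1]")
  (2 * a * s - 1) * p
}

#' Model right-hand side (reference implementation)
#'
#' Time derivatives of the four compartment densities. Written in plain R
#' as the documented reference of the model equations; [simulate_model()]
#' integrates an equivalent compiled version.
#'
#' The equations are, with healthy signal `s` and leukemic signal `sl`
#' (`sl = s` under `"model1"`, `sl = 1` under `"model2"`) and crowding
#' death rate `dbar * (c1 + l1)` acting on both mitotic compartments:
#' \deqn{c_1' = (2 a_c s - 1) p_c c_1 - \bar d (c_1+l_1) c_1}
#' \deqn{c_2' = 2 (1 - a_c s) p_c c_1 - d_c c_2}
#' \deqn{l_1' = (2 a_l s_l - 1) p_l l_1 - \bar d (c_1+l_1) l_1}
#' \deqn{l_2' = 2 (1 - a_l s_l) p_l l_1 - d_l l_2}
#'
#' @param state named numeric vector with components `c1`, `c2`, `l1`,
#'   `l2` (cells/kg), all `>= 0`.
#' @param params a [model_params()] object.
#' @param stimulated clamp the signal of cytokine-responsive compartments
#'   to 1 (exogenous stimulation)?
#' @return Named numeric vector of the four derivatives (cells/kg/day),
#'   with the signal `s` attached as attribute `"s"`.
#' @export
model_rhs <- function(state, params, stimulated = FALSE) {
  stopifnot(inherits(params, "leukdyn_params"))
  state <- state[c("c1", "c2", "l1", "l2")]
  if (any(!is.finite(state)) || any(state < 0))
    stop("state densities must be finite and >= 0")
  c1 <- state[["c1"]]; c2 <- state[["c2"]]
  l1 <- state[["l1"]]; l2 <- state[["l2"]]
  consumers <- if (params$variant == "model2") c2 else c2 + l2
  s <- feedback_signal(params$k, consumers, stimulated = stimulated)
  sl <- if (params$variant == "model2") 1 else s
  hc <- params$healthy; lc <- params$leukemic
  crowd <- params$dbar * (c1 + l1)
  out <- c(
    c1 = (2 * hc$a * s - 1) * hc$p * c1 - crowd * c1,
    c2 = 2 * (1 - hc$a * s) * hc$p * c1 - hc$d * c2,
    l1 = (2 * lc$a * sl - 1) * lc$p * l1 - crowd * l1,
    l2 = 2 * (1 - lc$a * sl) * lc$p * l1 - lc$d * l2
  )
  attr(out, "s") <- s
  out
}

#' Healthy steady state
#'
#' The positive equilibrium of the healthy subsystem (no leukemic cells).
#' Without crowding (`dbar = 0`) it has the closed form
#' `s* = 1/(2 a_c)`, `c2* = (2 a_c - 1)/k`, `c1* = d_c c2* / p_c`,
#' which requires `a_c > 1/2`. With `dbar > 0` the state is found as the
#' root of a scalar reduction of the steady-state conditions and verified
#' against the full right-hand side.
#'
#' @param params a [model_params()] object (only healthy-lineage, `k` and
#'   `dbar` entries are used).
#' @param method `"auto"` uses the closed form when `dbar = 0` and the
#'   numeric root otherwise; `"closed"` and `"numeric"` force one path
#'   (the closed form ignores crowding).
#' @param tol residual tolerance (relative, per day) for the numeric root.
#' @return Named state vector `c(c1, c2, l1 = 0, l2 = 0)` with the
#'   equilibrium signal attached as attribute `"s"`.
#' @examples
#' healthy_equilibrium(model_params(lineage_params(0.9, 0.5, 2.3)))
#' @export
healthy_equilibrium <- function(params,
                                method = c("auto", "closed", "numeric"),
                                tol = 1e-8) {
  stopifnot(inherits(params, "leukdyn_params"))
  method <- match.arg(method)
  hc <- params$healthy
  if (hc$a <= 0.5)
    stop("no positive healthy equilibrium: self-renewal a_c must exceed 0.5")
  if (method == "auto") method <- if (params$dbar == 0) "closed" else "numeric"

  if (method == "closed") {
    s <- 1 / (2 * hc$a)
    c2 <- (2 * hc$a - 1) / params$k
    c1 <- hc$d * c2 / hc$p
  } else {
    ## parametrize by c1: stationarity of c1 fixes s, stationarity of c2
    ## fixes c2, and the signal equation becomes a scalar root problem
    s_of <- function(c1) (1 + params$dbar * c1 / hc$p) / (2 * hc$a)
    c2_of <- function(c1) 2 * (1 - hc$a * s_of(c1)) * hc$p * c1 / hc$d
    g <- function(c1) 1 / (1 + params$k * c2_of(c1)) - s_of(c1)
    c1_ref <- hc$d * (2 * hc$a - 1) / (params$k * hc$p)
    upper <- c1_ref * 10
    if (params$dbar > 0)
      upper <- min(upper, (2 * hc$a - 1) * hc$p / params$dbar * 0.999999)
    root <- stats::uniroot(g, lower = c1_ref * 1e-8, upper = upper,
                           tol = c1_ref * 1e-14)
    c1 <- root$root
    s <- s_of(c1)
    c2 <- c2_of(c1)
  }
  state <- c(c1 = c1, c2 = c2, l1 = 0, l2 = 0)
  resid <- model_rhs(state, params)
  if (max(abs(resid) / pmax(state, 1)) > tol)
    stop("healthy equilibrium residual exceeds tolerance")
  attr(state, "s") <- s
  state
}

#' Marrow blast fraction
#'
#' Leukemic share `l1 / (c1 + l1)` of the mitotic (marrow-resident) cell
#' pool, the quantity reported by bone-marrow aspiration.
#'
#' @param state a named state vector, a `leukdyn_trajectory`, or a
#'   data frame with columns `c1` and `l1`.
#' @return Blast fraction(s) in `[0, 1]`.
#' @examples
#' blast_fraction(c(c1 = 9e8, c2 = 0, l1 = 1e8, l2 = 0))  # 0.1
#' @export
blast_fraction <- function(state) {
  if (is.data.frame(state)) {
    c1 <- state$c1; l1 <- state$l1
  } else {
    c1 <- state[["c1"]]; l1 <- state[["l1"]]
  }
  tot <- c1 + l1
  if (any(tot <= 0)) stop("blast fraction undefined: empty marrow (c1 + l1 = 0)")
  l1 / tot
}

## Low-level integrator over one segment with a fixed stimulation flag.
## Returns the deSolve matrix (t, c1, c2, l1, l2, s).
.integrate_segment <- function(params, y0, times, stimulated = FALSE,
                               rootfunc = NULL, thr = 0, trigger = 0,
                               rtol = 1e-8, atol = 1e-6) {
  pv <- .parm_vector(params, stimulated = stimulated, thr = thr,
                     trigger = trigger)
  y0 <- setNames(as.numeric(y0[c("c1", "c2", "l1", "l2")]),
                 c("c1", "c2", "l1", "l2"))
  args <- list(y = y0, times = times, func = "leuk_derivs", parms = pv,
               dllname = "leukdyn", initfunc = "leuk_initmod",
               nout = 1L, outnames = "s", rtol = rtol, atol = atol,
               maxsteps = 50000L)
  out <- if (is.null(rootfunc)) {
    do.call(deSolve::lsoda, args)
  } else {
    do.call(deSolve::lsodar, c(args, list(rootfunc = rootfunc, nroot = 1L)))
  }
  m <- unclass(out)
  if (any(!is.finite(m))) {
    ok <- stats::complete.cases(m)
    last <- if (any(ok)) m[max(which(ok)), ] else y0
    stop(errorCondition("integration failed (non-finite state)",
                        class = "leukdyn_integration_error",
                        last_state = last))
  }
  ## clear tiny negative undershoot; densities below 1e-12 cells/kg are
  ## treated as extinct
  vals <- m[, 2:5, drop = FALSE]
  undershoot <- max(1e3 * atol, 1e-9 * max(abs(vals)))
  vals[vals < 0 & vals > -undershoot] <- 0
  if (any(vals < 0))
    stop(errorCondition("integration failed: negative density beyond tolerance",
                        class = "leukdyn_integration_error",
                        last_state = m[nrow(m), ]))
  vals[vals < 1e-12] <- 0
  m[, 2:5] <- vals
  attr(m, "troot") <- attributes(out)$troot
  m
}

#' Simulate a model trajectory
#'
#' Integrates the four-compartment system with an adaptive stiff-capable
#' solver (relative tolerance `1e-8`, absolute tolerance `1e-6` cells/kg).
#' If a [stimulation_protocol()] is supplied the integration is split into
#' segments so that the signal clamp is active exactly during
#' `[t_start, t_start + duration]`.
#'
#' @param params a [model_params()] object.
#' @param init initial state; defaults to [healthy_equilibrium()].
#' @param t_end simulation horizon in days.
#' @param protocol optional [stimulation_protocol()].
#' @param times optional explicit output times (days, starting at 0);
#'   defaults to at least one stored point per day.
#' @param rtol,atol solver tolerances.
#' @return A `leukdyn_trajectory`: a data frame with columns `t`, `c1`,
#'   `c2`, `l1`, `l2`, `s` and `blast_fraction`, with the parameter set and
#'   protocol attached as attributes.
#' @examples
#' p <- model_params(lineage_params(0.99, 1, 2.3), variant = "model2")
#' tr <- simulate_model(p, t_end = 30)
#' tail(tr, 3)
#' @export
simulate_model <- function(params, init = NULL, t_end, protocol = NULL,
                           times = NULL, rtol = 1e-8, atol = 1e-6) {
  stopifnot(inherits(params, "leukdyn_params"), t_end > 0)
  if (is.null(init)) init <- healthy_equilibrium(params)
  if (is.null(times)) times <- seq(0, t_end, by = min(1, t_end / 100))
  if (is.unsorted(times, strictly = TRUE)) stop("`times` must be strictly increasing")

  segments <- list(list(times = times, stim = FALSE))
  if (!is.null(protocol)) {
    stopifnot(inherits(protocol, "leukdyn_protocol"))
    brk <- c(protocol$t_start, protocol$t_start + protocol$duration)
    brk <- brk[brk > min(times) & brk < max(times)]
    edges <- sort(unique(c(min(times), brk, max(times))))
    segments <- lapply(seq_len(length(edges) - 1L), function(i) {
      tt <- sort(unique(c(edges[i], times[times > edges[i] & times < edges[i + 1L]],
                          edges[i + 1L])))
      mid <- (edges[i] + edges[i + 1L]) / 2
      list(times = tt,
           stim = mid >= protocol$t_start &&
                  mid <= protocol$t_start + protocol$duration)
    })
  }

  y <- init
  pieces <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    m <- .integrate_segment(params, y, segments[[i]]$times,
                            stimulated = segments[[i]]$stim,
                            rtol = rtol, atol = atol)
    y <- m[nrow(m), 2:5]
    pieces[[i]] <- if (i == 1L) m else m[-1L, , drop = FALSE]
  }
  m <- do.call(rbind, pieces)
  df <- as.data.frame(m)
  names(df) <- c("t", "c1", "c2", "l1", "l2", "s")
  df$blast_fraction <- ifelse(df$c1 + df$l1 > 0, df$l1 / (df$c1 + df$l1), NA_real_)
  structure(df, params = params, protocol = protocol,
            class = c("leukdyn_trajectory", "data.frame"))
}

#' @export
print.leukdyn_trajectory <- function(x, ...) {
  cat(sprintf("leukdyn trajectory: %d time points over [%g, %g] days\n",
              nrow(x), min(x$t), max(x$t)))
  print.data.frame(utils::head(as.data.frame(x), 5), row.names = FALSE)
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Plot a trajectory
#'
#' Compartment densities over time on a log scale, with the blast fraction
#' available through `which = "blast"`.
#'
#' @param x a `leukdyn_trajectory`.
#' @param which `"compartments"` or `"blast"`.
#' @param ... passed to [plot()].
#' @export
plot.leukdyn_trajectory <- function(x, which = c("compartments", "blast"), ...) {
  which <- match.arg(which)
  if (which == "blast") {
    plot(x$t, x$blast_fraction, type = "l", xlab = "time (days)",
         ylab = "marrow blast fraction", ...)
  } else {
    cols <- c(c1 = "steelblue", c2 = "skyblue3", l1 = "firebrick", l2 = "salmon")
    yl <- range(pmax(as.matrix(x[, names(cols)]), 1e-3))
    plot(x$t, pmax(x$c1, 1e-3), type = "l", log = "y", ylim = yl,
         col = cols[1], xlab = "time (days)", ylab = "cells/kg", ...)
    for (nm in names(cols)[-1]) lines(x$t, pmax(x[[nm]], 1e-3), col = cols[nm])
    legend("bottomright", legend = names(cols), col = cols, lty = 1, bty = "n")
  }
  invisible(x)
}

#' Write a trajectory as tidy CSV
#'
#' Columns: `t_days`, `c1`, `c2`, `l1`, `l2`, `s`, `blast_fraction`.
#'
#' @param trajectory a `leukdyn_trajectory`.
#' @param path output file.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  names(df)[names(df) == "t"] <- "t_days"
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
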