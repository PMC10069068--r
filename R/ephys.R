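# Units: time ms, voltage mV, current pA, resistance MOhm, conductance nS,
# capacitance pF. Handy identities: dV[mV] = I[pA] * R[MOhm] * 1e-3;
# tau[ms] = R[MOhm] * C[pF] * 1e-3; Gm[nS] = 1000 / Rm[MOhm].

#' Current-clamp step protocol
#'
#' Square current steps from a zero-current baseline, the family used to
#' estimate the input resistance (steps from -800 to +400 pA in 400 pA
#' increments by default).
#'
#' @param steps step amplitudes (pA), one sweep each.
#' @param baseline,step_dur,tail segment durations (ms).
#' @param dt sampling interval (ms); default 0.02 ms = 50 kHz.
#' @return protocol list.
#' @export
cc_protocol <- function(steps = seq(-800, 400, by = 400), baseline = 100,
                        step_dur = 300, tail = 100, dt = 0.02) {
  list(mode = "cc", steps = steps, baseline = baseline, step_dur = step_dur,
       tail = tail, dt = dt, holding = 0)
}

#' Voltage-clamp step protocol
#'
#' Voltage steps from a holding potential, covering the -10 to -130 mV
#' steady-state I-V range by default; the -10 mV hyperpolarizing step used
#' for the resting conductance is included.
#'
#' @param delta_mv step amplitudes relative to holding (mV).
#' @param holding holding potential (mV).
#' @param baseline,step_dur,tail segment durations (ms).
#' @param dt sampling interval (ms).
#' @return protocol list.
#' @export
vc_protocol <- function(delta_mv = seq(-10, -130, by = -20), holding = -85,
                        baseline = 50, step_dur = 200, tail = 50, dt = 0.02) {
  list(mode = "vc", steps = delta_mv, baseline = baseline,
       step_dur = step_dur, tail = tail, dt = dt, holding = holding)
}

#' Simulate passive (RC) membrane sweeps
#'
#' Single-compartment passive model: membrane resistance `Rm` in parallel
#' with capacitance `Cm`, resting at `Vrest`. In current clamp each step
#' relaxes exponentially to `Vrest + I*Rm` with time constant `Rm*Cm`; in
#' voltage clamp the steady-state current is ohmic, `(Vcmd - Vrest)/Rm`,
#' with a capacitive settling transient (charge `dV*Cm` delivered over a
#' fixed clamp settling constant) at each command change. Gaussian noise is
#' added to the response; deterministic per seed.
#'
#' @param Rm membrane resistance (MΩ).
#' @param Cm membrane capacitance (pF).
#' @param Vrest resting potential (mV).
#' @param protocol a [cc_protocol()] or [vc_protocol()].
#' @param noise_sd response noise sd (mV in current clamp, pA in voltage
#'   clamp).
#' @param seed integer seed.
#' @param settle_tau voltage-clamp settling constant (ms).
#' @return a `pv_sweeps` object: `time`, `command` and `response` matrices
#'   (samples x sweeps), `mode`, `holding`, `dt`.
#' @export
simulate_rc_sweeps <- function(Rm, Cm, Vrest, protocol = cc_protocol(),
                               noise_sd = 0, seed = 1L, settle_tau = 0.2) {
  stopifnot(Rm > 0, Cm > 0)
  dt <- protocol$dt
  n_bl <- round(protocol$baseline / dt)
  n_st <- round(protocol$step_dur / dt)
  n_tl <- round(protocol$tail / dt)
  n <- n_bl + n_st + n_tl
  time <- (seq_len(n) - 1) * dt
  ns <- length(protocol$steps)
  command <- response <- matrix(0, n, ns)
  tau <- Rm * Cm * 1e-3  # ms

  for (s in seq_len(ns)) {
    if (protocol$mode == "cc") {
      lev <- c(0, protocol$steps[s], 0)
      cmd <- rep(lev, c(n_bl, n_st, n_tl))
      v <- numeric(n)
      v0 <- Vrest
      i0 <- 1L
      for (seg in seq_along(lev)) {
        nseg <- c(n_bl, n_st, n_tl)[seg]
        if (nseg == 0) next
        vinf <- Vrest + lev[seg] * Rm * 1e-3
        tt <- (seq_len(nseg) - 1) * dt
        v[i0:(i0 + nseg - 1)] <- vinf + (v0 - vinf) * exp(-tt / tau)
        v0 <- vinf + (v0 - vinf) * exp(-nseg * dt / tau)
        i0 <- i0 + nseg
      }
      command[, s] <- cmd
      response[, s] <- v
    } else {
      dv <- protocol$steps[s]
      lev <- protocol$holding + c(0, dv, 0)
      cmd <- rep(lev, c(n_bl, n_st, n_tl))
      i <- (cmd - Vrest) / Rm * 1e3  # pA
      # capacitive transients at the two command changes
      for (edge in c(n_bl, n_bl + n_st)) {
        if (edge < 1 || edge >= n) next
        dV <- cmd[edge + 1] - cmd[edge]
        tt <- (seq_len(n - edge) - 1) * dt
        i[(edge + 1):n] <- i[(edge + 1):n] +
          dV * Cm / settle_tau * exp(-tt / settle_tau)
      }
      command[, s] <- cmd
      response[, s] <- i
    }
  }
  if (noise_sd > 0)
    response <- response + with_seed(seed, {
      matrix(rnorm(n * ns, sd = noise_sd), n, ns)
    })
  structure(list(time = time, command = command, response = response,
                 mode = protocol$mode, holding = protocol$holding, dt = dt,
                 true_params = list(Rm = Rm, Cm = Cm, Vrest = Vrest)),
            class = "pv_sweeps")
}

# coefficient of determination without summary.lm (which warns on the
# noise-free fits these pipelines routinely produce)
fit_r_squared <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / sst
}

# constant-command runs of one sweep: data.frame(start, end, level)
command_runs <- function(cmd) {
  r <- rle(cmd)
  ends <- cumsum(r$lengths)
  data.frame(start = c(1L, head(ends, -1) + 1L), end = ends,
             level = r$values)
}

# steady-state mean over the terminal fraction of a run
steady_mean <- function(y, start, end, window = 0.2) {
  i0 <- end - max(1L, floor((end - start + 1L) * window)) + 1L
  mean(y[i0:end])
}

#' Resting membrane potential
#'
#' Mean of the baseline samples of current-clamp traces during zero-current
#' injection. Samples immediately after a command change are discarded
#' (membrane still settling).
#'
#' @param sweeps a `pv_sweeps` in current-clamp mode.
#' @param settle_ms samples within this window after a command change are
#'   excluded from baselines that follow a step.
#' @return Vm in mV (uncorrected for the junction potential).
#' @export
resting_potential <- function(sweeps, settle_ms = 50) {
  if (sweeps$mode != "cc") stop("resting potential needs current-clamp sweeps")
  vals <- numeric(0)
  for (s in seq_len(ncol(sweeps$command))) {
    runs <- command_runs(sweeps$command[, s])
    z <- runs[runs$level == 0, , drop = FALSE]
    for (r in seq_len(nrow(z))) {
      st <- z$start[r]
      if (st > 1L) st <- min(st + round(settle_ms / sweeps$dt), z$end[r])
      vals <- c(vals, sweeps$response[st:z$end[r], s])
    }
  }
  if (!length(vals)) stop("no zero-current baseline segment found")
  mean(vals)
}

#' Input resistance from a current-step family
#'
#' Slope of the steady-state voltage deflection against injected current
#' over the linear range. The linear range is the largest contiguous subset
#' of steps (ordered by amplitude, >= 3 points) whose linear fit reaches
#' R² >= 0.99; saturating extreme steps are thereby excluded.
#'
#' @param sweeps a `pv_sweeps` in current-clamp mode.
#' @param window terminal fraction of each step used as steady state.
#' @param r2_min linear-range screening threshold.
#' @return Rin in MΩ.
#' @export
input_resistance <- function(sweeps, window = 0.2, r2_min = 0.99) {
  iv <- cc_step_table(sweeps, window)
  if (nrow(iv) < 3L) stop("need at least 3 usable current steps")
  iv <- iv[order(iv$di), ]
  best <- NULL
  for (size in seq(nrow(iv), 3L)) {
    for (st in seq_len(nrow(iv) - size + 1L)) {
      sub <- iv[st:(st + size - 1L), ]
      fit <- lm(dv ~ di, data = sub)
      r2 <- fit_r_squared(fit, sub$dv)
      if (r2 >= r2_min) { best <- fit; break }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) best <- lm(dv ~ di, data = iv)  # fall back: full fit
  unname(coef(best)[2]) * 1e3  # mV/pA -> MΩ
}

# per-sweep steady-state deflection table for current-clamp families
cc_step_table <- function(sweeps, window = 0.2) {
  if (sweeps$mode != "cc") stop("need current-clamp sweeps")
  out <- NULL
  for (s in seq_len(ncol(sweeps$command))) {
    runs <- command_runs(sweeps$command[, s])
    stp <- runs[runs$level != 0, , drop = FALSE]
    base <- runs[runs$level == 0, , drop = FALSE]
    if (!nrow(base)) next
    v0 <- steady_mean(sweeps$response[, s], base$start[1], base$end[1], window)
    if (!nrow(stp)) {
      out <- rbind(out, data.frame(di = 0, dv = 0, sweep = s))
      next
    }
    r <- which.max(stp$end - stp$start)  # main step of the sweep
    dv <- steady_mean(sweeps$response[, s], stp$start[r], stp$end[r],
                      window) - v0
    out <- rbind(out, data.frame(di = stp$level[r], dv = dv, sweep = s))
  }
  out
}

#' Resting membrane conductance
#'
#' `Gm = dI/dV` for a 10 mV hyperpolarizing voltage-clamp step from the
#' holding potential, using the steady-state current.
#'
#' @param sweeps a `pv_sweeps` in voltage-clamp mode.
#' @param window terminal fraction of the step used as steady state.
#' @return Gm in nS.
#' @export
resting_conductance <- function(sweeps, window = 0.2) {
  if (sweeps$mode != "vc") stop("resting conductance needs voltage-clamp sweeps")
  for (s in seq_len(ncol(sweeps$command))) {
    runs <- command_runs(sweeps$command[, s])
    stp <- runs[runs$level != sweeps$holding, , drop = FALSE]
    base <- runs[runs$level == sweeps$holding, , drop = FALSE]
    if (!nrow(stp) || !nrow(base)) next
    r <- which.max(stp$end - stp$start)
    dvstep <- stp$level[r] - sweeps$holding
    if (abs(dvstep + 10) < 0.5) {
      i0 <- steady_mean(sweeps$response[, s], base$start[1], base$end[1],
                        window)
      i1 <- steady_mean(sweeps$response[, s], stp$start[r], stp$end[r],
                        window)
      return((i1 - i0) / dvstep)  # pA / mV = nS
    }
  }
  stop("no -10 mV step from holding found")
}

#' Steady-state current-voltage relation
#'
#' Per-sweep steady-state current (mean over the terminal window of each
#' voltage step) against the command potential, with the R² of a linear fit
#' as the linearity metric — passive cells give a linear I-V.
#'
#' @param sweeps a `pv_sweeps` in voltage-clamp mode.
#' @param window terminal fraction of each step (must not exceed 1).
#' @return data.frame (v_mv, i_pa) with attribute `r_squared`.
#' @export
steady_state_iv <- function(sweeps, window = 0.2) {
  if (sweeps$mode != "vc") stop("steady-state I-V needs voltage-clamp sweeps")
  if (window <= 0 || window > 1) stop("window must lie in (0, 1]")
  out <- NULL
  for (s in seq_len(ncol(sweeps$command))) {
    runs <- command_runs(sweeps$command[, s])
    stp <- runs[runs$level != sweeps$holding, , drop = FALSE]
    if (!nrow(stp)) next
    r <- which.max(stp$end - stp$start)
    out <- rbind(out, data.frame(
      v_mv = stp$level[r],
      i_pa = steady_mean(sweeps$response[, s], stp$start[r], stp$end[r],
                         window)))
  }
  if (is.null(out) || nrow(out) < 2L) stop("not enough voltage steps")
  out <- out[order(out$v_mv), ]
  fit <- lm(i_pa ~ v_mv, data = out)
  attr(out, "r_squared") <- fit_r_squared(fit, out$i_pa)
  attr(out, "slope_ns") <- unname(coef(fit)[2])  # pA/mV = nS
  out
}

#' Membrane time constant by the area method
#'
#' For each current step, tau = integral of (Vss - V(t)) dt / (Vss - V0),
#' exact for a single-exponential relaxation and unbiased under zero-mean
#' noise. Returns the median over usable steps.
#'
#' @param sweeps a `pv_sweeps` in current-clamp mode.
#' @param window terminal steady-state fraction.
#' @return tau in ms.
#' @export
membrane_tau <- function(sweeps, window = 0.2) {
  if (sweeps$mode != "cc") stop("need current-clamp sweeps")
  taus <- numeric(0)
  for (s in seq_len(ncol(sweeps$command))) {
    runs <- command_runs(sweeps$command[, s])
    stp <- runs[runs$level != 0, , drop = FALSE]
    base <- runs[runs$level == 0, , drop = FALSE]
    if (!nrow(stp) || !nrow(base)) next
    r <- which.max(stp$end - stp$start)
    v <- sweeps$response[, s]
    v0 <- steady_mean(v, base$start[1], base$end[1], window)
    vss <- steady_mean(v, stp$start[r], stp$end[r], window)
    if (abs(vss - v0) < 1e-9) next
    seg <- v[stp$start[r]:stp$end[r]]
    tau0 <- sum(vss - seg) * sweeps$dt / (vss - v0)
    # second pass over ~10 time constants: integrating the full step only
    # accumulates noise once the relaxation is over
    nwin <- min(length(seg), max(16L, ceiling(10 * tau0 / sweeps$dt)))
    tau1 <- sum(vss - seg[seq_len(nwin)]) * sweeps$dt / (vss - v0)
    taus <- c(taus, tau1)
  }
  if (!length(taus)) stop("no usable step for the time constant")
  median(taus)
}

#' Passive membrane properties from sweep families
#'
#' Bundles the four variables used to characterize a cell: resting potential
#' (current clamp, zero current), input resistance (current-step family),
#' resting conductance (-10 mV voltage step) and capacitance (tau / Rin from
#' the step relaxation — an artifact convention, since tau and Rin are the
#' directly fitted quantities).
#'
#' @param cc_sweeps current-clamp `pv_sweeps`.
#' @param vc_sweeps voltage-clamp `pv_sweeps` (optional; Gm is NA without).
#' @return object of class `pv_membrane_props` with fields vm, rin, gm, cm
#'   and the `ljp_corrected` flag (FALSE until [correct_ljp()] is applied).
#' @export
membrane_props <- function(cc_sweeps, vc_sweeps = NULL) {
  vm <- resting_potential(cc_sweeps)
  rin <- input_resistance(cc_sweeps)
  tau <- membrane_tau(cc_sweeps)
  gm <- if (!is.null(vc_sweeps)) resting_conductance(vc_sweeps) else NA_real_
  structure(list(vm = vm, rin = rin, gm = gm,
                 cm = tau / rin * 1e3,  # ms/MΩ = nF -> pF
                 tau = tau, ljp_corrected = FALSE),
            class = "pv_membrane_props")
}

#' @export
print.pv_membrane_props <- function(x, ...) {
  cat("<membrane properties>",
      if (x$ljp_corrected) "(LJP-corrected)" else "(uncorrected)", "\n")
  cat(sprintf("  Vm  %8.2f mV\n  Rin %8.2f MOhm\n  Gm  %8.2f nS\n  Cm  %8.2f pF\n",
              x$vm, x$rin, x$gm, x$cm))
  invisible(x)
}

#' Liquid junction potential correction
#'
#' Adds the (negative) junction potential to measured voltages: with the
#' default -15 mV, a measured -71.47 mV reports as -86.47 mV. A
#' `pv_membrane_props` object carries a flag so the correction cannot be
#' applied twice.
#'
#' @param x numeric voltages (mV) or a `pv_membrane_props`.
#' @param ljp junction potential in mV, default -15.
#' @return corrected object of the same type.
#' @export
correct_ljp <- function(x, ljp = -15) {
  if (inherits(x, "pv_membrane_props")) {
    if (isTRUE(x$ljp_corrected))
      stop("voltages are already junction-potential corrected")
    x$vm <- x$vm + ljp
    x$ljp_corrected <- TRUE
    x
  } else {
    x + ljp
  }
}

#' Recording solution
#'
#' Ion concentrations, valences and temperature of a solution, as needed for
#' equilibrium-potential calculations.
#'
#' @param ions named concentrations in mM (e.g. `c(K = 140)`).
#' @param temperature K.
#' @param valence named integer valences; defaults cover K, Na, Cl, Ca.
#' @return object of class `pv_solution`.
#' @export
solution <- function(ions, temperature = 306.15,
                     valence = c(K = 1L, Na = 1L, Cl = -1L, Ca = 2L)) {
  if (any(ions <= 0)) stop("concentrations must be > 0")
  if (temperature <= 0) stop("temperature must be > 0 K")
  structure(list(ions = ions, temperature = temperature, valence = valence),
            class = "pv_solution")
}

#' Nernst equilibrium potential
#'
#' `E = (R*T)/(z*F) * ln([ion]_out / [ion]_in)` in mV, evaluated at the
#' inside solution's temperature. With the standard internal solution
#' (130 mM K-gluconate + 10 mM KCl = 140 mM K) against 3 mM external K at
#' 306.15 K this gives -101.39 mV; the modified internal (135 mM K) gives
#' -100.42 mV (0.96 mV difference).
#'
#' @param ion ion name present in both solutions.
#' @param inside,outside [solution()] objects.
#' @return equilibrium potential in mV.
#' @export
nernst <- function(ion, inside, outside) {
  for (s in list(inside, outside))
    if (!ion %in% names(s$ions)) stop("ion '", ion, "' missing from solution")
  if (!ion %in% names(inside$valence)) stop("no valence for ", ion)
  zi <- inside$valence[[ion]]
  zo <- if (ion %in% names(outside$valence)) outside$valence[[ion]] else zi
  if (zi != zo) stop("valence mismatch for ", ion)
  if (zi == 0) stop("valence must be nonzero")
  ci <- inside$ions[[ion]]
  co <- outside$ions[[ion]]
  if (ci <= 0 || co <= 0) stop("concentrations must be > 0")
  Rgas <- 8.31446261815324    # J / (mol K)
  Faraday <- 96485.33212      # C / mol
  1000 * Rgas * inside$temperature / (zi * Faraday) * log(co / ci)
}

#' PCA of the four membrane variables
#'
#' Principal component analysis of standardized Vm, Gm, Rin and Cm across
#' cells, with an overlap summary for two groups: the distance between the
#' group centroids in the PC1-PC2 plane compared with the mean within-group
#' spread (RMS distance to the own centroid). Overlapping groups have a
#' centroid distance below the spread.
#'
#' @param records data.frame with columns vm, gm, rin, cm (>= 3 rows).
#' @param group optional factor for the overlap summary.
#' @return list with `scores`, `loadings`, `explained` (variances, summing
#'   to the number of variables) and optional `group_summary`.
#' @importFrom stats prcomp
#' @export
pca_membrane_props <- function(records, group = NULL) {
  vars <- c("vm", "gm", "rin", "cm")
  miss <- setdiff(vars, names(records))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  x <- as.matrix(records[, vars])
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3L) stop("need at least 3 complete records")
  cst <- vars[apply(x, 2, sd) == 0]
  if (length(cst)) stop("constant variable: ", paste(cst, collapse = ", "))
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  out <- list(scores = p$x, loadings = p$rotation,
              explained = p$sdev^2)
  if (!is.null(group)) {
    g <- factor(group)
    if (nlevels(g) == 2L) {
      sc <- p$x[, 1:2, drop = FALSE]
      cents <- lapply(levels(g), function(l)
        colMeans(sc[g == l, , drop = FALSE]))
      dist_c <- sqrt(sum((cents[[1]] - cents[[2]])^2))
      spread <- mean(vapply(levels(g), function(l) {
        m <- sc[g == l, , drop = FALSE]
        sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
      }, numeric(1)))
      out$group_summary <- list(centroid_distance = dist_c,
                                within_spread = spread,
                                overlapping = dist_c < spread)
    }
  }
  out
}
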