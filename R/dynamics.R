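# Langevin dynamics, constant-velocity pulling, temperature scans and the
# perturb-and-relax protocol, all on the C-alpha Go model.

#' Thermostat and integrator settings
#'
#' Reduced units throughout: temperature in units of epsilon/k_B, time in LJ
#' time units.  Defaults follow the standard coarse-grained setup: time step
#' 0.004 and a Langevin time constant of 12 (friction = 1/12).
#'
#' @param temperature reduced temperature (>= 0).
#' @param timeConstant Langevin thermostat time constant (inverse friction);
#'   `Inf` disables the thermostat.
#' @param timeStep integration time step.
#' @param seed integer seed for the thermostat noise.
#' @return A list of settings.
#' @export
thermostatSettings <- function(temperature, timeConstant = 12, timeStep = 0.004,
                               seed = 1L) {
  stopifnot(temperature >= 0, timeStep > 0, timeConstant > 0)
  list(temperature = temperature,
       gamma = if (is.finite(timeConstant)) 1 / timeConstant else 0,
       timeStep = timeStep, seed = as.integer(seed))
}

#' Constant-velocity pulling protocol
#'
#' Both termini are tethered by harmonic springs of stiffness `k`; the
#' reference point of the pulled (C-terminal) bead moves with constant
#' speed `v` along the terminus-to-terminus axis fixed at setup.  The run
#' ends when the change in tether separation reaches `L`.
#'
#' @param k spring constant (reduced energy / nm^2).
#' @param v pulling speed (nm per LJ time unit).
#' @param L maximum extension (nm); `NULL` for the chain-length default
#'   30 nm x (n/110) applied at run time.
#' @param pulledBead,fixedBead bead indices; default C- and N-terminus.
#' @return A list describing the protocol.
#' @export
pullingProtocol <- function(k = 837, v = 0.01, L = NULL,
                            pulledBead = NULL, fixedBead = 1L) {
  stopifnot(k > 0, v > 0)
  list(k = k, v = v, L = L, pulledBead = pulledBead, fixedBead = fixedBead)
}

.traj_from_run <- function(run, runId, metadata) {
  new("Trajectory", coords = run$frames, time = run$time,
      extension = run$extension, force = run$force,
      potential = run$potential, kinetic = run$kinetic,
      runId = runId, metadata = metadata)
}

#' Run Langevin dynamics
#'
#' BAOAB Langevin integration of a [GoModel-class].  With zero friction
#' (`timeConstant = Inf`) and zero temperature the scheme reduces to
#' velocity Verlet and conserves energy.
#'
#' @param model a [GoModel-class].
#' @param thermostat settings from [thermostatSettings()].
#' @param nSteps number of integration steps.
#' @param reportEvery snapshot cadence in steps (default 1000).
#' @param x0,v0 optional initial coordinates/velocities (default: native
#'   coordinates, zero velocities).
#' @return A [Trajectory-class] (the frame at step 0 is included).
#' @export
runLangevin <- function(model, thermostat, nSteps, reportEvery = 1000L,
                        x0 = NULL, v0 = NULL) {
  stopifnot(nSteps > 0)
  if (is.null(x0)) x0 <- coords(model@structure)
  run <- .go_dynamics(.model_cpp(model), .num_mat(x0, 3),
                      if (is.null(v0)) NULL else .num_mat(v0, 3),
                      thermostat$timeStep, thermostat$gamma,
                      thermostat$temperature, as.integer(nSteps),
                      as.integer(reportEvery), as.numeric(thermostat$seed),
                      NULL, NULL)
  .traj_from_run(run, runId = paste0("langevin-", thermostat$seed),
                 metadata = list(kind = "langevin", thermostat = thermostat,
                                 nSteps = nSteps,
                                 x_final = run$x_final, v_final = run$v_final))
}

#' Constant-velocity pulling run
#'
#' Steered run with both termini tethered (see [pullingProtocol()]); frames
#' carry time, extension delta-x and the instantaneous spring force along
#' the pulling axis.  For a folded start near 0.9 Tf the force-extension
#' record shows the sawtooth rise-and-drop pattern of serial unfolding
#' events.
#'
#' @inheritParams runLangevin
#' @param protocol a [pullingProtocol()] list.
#' @param maxSteps safety cap on steps (default: enough to reach `L`).
#' @return A [Trajectory-class] with force-extension records.
#' @export
runPull <- function(model, protocol, thermostat, reportEvery = 1000L,
                    x0 = NULL, maxSteps = NULL) {
  n <- nrow(model@structure@atoms)
  if (is.null(x0)) x0 <- coords(model@structure)
  pulled <- if (is.null(protocol$pulledBead)) n else protocol$pulledBead
  fixed <- protocol$fixedBead
  stopifnot(pulled >= 1, pulled <= n, fixed >= 1, fixed <= n, pulled != fixed)
  L <- if (is.null(protocol$L)) 30 * n / 110 else protocol$L
  if (is.null(maxSteps))
    maxSteps <- ceiling(1.5 * L / protocol$v / thermostat$timeStep)
  run <- .go_dynamics(.model_cpp(model), .num_mat(x0, 3), NULL,
                      thermostat$timeStep, thermostat$gamma,
                      thermostat$temperature, as.integer(maxSteps),
                      as.integer(reportEvery), as.numeric(thermostat$seed),
                      list(k = protocol$k, speed = protocol$v,
                           pulled = as.integer(pulled),
                           fixed = as.integer(fixed), L = L),
                      NULL)
  .traj_from_run(run, runId = paste0("pull-", thermostat$seed),
                 metadata = list(kind = "pull", thermostat = thermostat,
                                 protocol = protocol, L = L,
                                 x_final = run$x_final))
}

#' Thermal melting scan
#'
#' Direct mode runs independent Langevin simulations at each temperature
#' (optionally several replicates) and records the Q time series.  REMD mode
#' runs one replica per temperature with Metropolis temperature-swap
#' attempts every `swapEvery` steps; the swap acceptance rate is recorded in
#' the result's `series` attribute.
#'
#' @param model a [GoModel-class].
#' @param temperatures increasing vector of reduced temperatures (>= 3
#'   values spanning the transition).
#' @param nSteps steps per run (per replica in REMD mode).
#' @param nRuns replicate runs per temperature (direct mode).
#' @param mode `"direct"` or `"remd"`.
#' @param equilFraction initial fraction of each series discarded before
#'   averaging (default 0.5).
#' @param reportEvery,swapEvery snapshot / swap-attempt cadence in steps.
#' @param seed integer seed.
#' @return A [MeltingCurve-class]; `series` holds the per-temperature Q
#'   series and, for REMD, the swap acceptance rate.
#' @export
runTemperatureScan <- function(model, temperatures, nSteps, nRuns = 1L,
                               mode = c("direct", "remd"),
                               equilFraction = 0.5,
                               reportEvery = 200L, swapEvery = 1000L,
                               seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(temperatures) >= 3, !is.unsorted(temperatures, strictly = TRUE))
  map <- model@map
  if (mode == "direct") {
    series <- lapply(seq_along(temperatures), function(ti) {
      qs <- lapply(seq_len(nRuns), function(r) {
        th <- thermostatSettings(temperatures[ti],
                                 seed = seed + 1000L * ti + r)
        traj <- runLangevin(model, th, nSteps, reportEvery)
        trajectoryQ(traj, map)
      })
      do.call(rbind, qs)
    })
  } else {
    series <- .remd_scan(model, temperatures, nSteps, reportEvery, swapEvery, seed)
  }
  keep <- function(m) {
    nk <- ncol(m)
    m[, seq.int(floor(equilFraction * nk) + 1L, nk), drop = FALSE]
  }
  meanQ <- vapply(series[seq_along(temperatures)],
                  function(m) mean(keep(m)), numeric(1))
  semQ <- vapply(series[seq_along(temperatures)], function(m) {
    v <- as.numeric(t(keep(m)))
    if (length(v) >= 64) suppressWarnings(blockAverageSEM(v))
    else sd(v) / sqrt(length(v))
  }, numeric(1))
  new("MeltingCurve", temperatures = temperatures,
      meanQ = pmin(1, pmax(0, meanQ)), semQ = semQ, series = series)
}

# replica-exchange: one replica per temperature, Metropolis swaps between
# neighbouring temperatures (k_B = 1)
.remd_scan <- function(model, temperatures, nSteps, reportEvery, swapEvery, seed) {
  nrep <- length(temperatures)
  mc <- .model_cpp(model)
  x <- lapply(seq_len(nrep), function(i) coords(model@structure))
  v <- vector("list", nrep)
  qs <- vector("list", nrep)  # per-temperature Q series
  for (i in seq_len(nrep)) qs[[i]] <- numeric()
  nchunks <- max(1L, floor(nSteps / swapEvery))
  att <- acc <- 0L
  set.seed(seed)
  for (ch in seq_len(nchunks)) {
    pe <- numeric(nrep)
    for (i in seq_len(nrep)) {
      th <- thermostatSettings(temperatures[i],
                               seed = seed + 7919L * ch + i)
      run <- .go_dynamics(mc, .num_mat(x[[i]], 3),
                          if (is.null(v[[i]])) NULL else .num_mat(v[[i]], 3),
                          th$timeStep, th$gamma, th$temperature,
                          as.integer(swapEvery), as.integer(reportEvery),
                          as.numeric(th$seed), NULL, NULL)
      x[[i]] <- run$x_final; v[[i]] <- run$v_final
      nf <- dim(run$frames)[3]
      qv <- vapply(seq_len(nf), function(k)
        nativeFraction(run$frames[, , k], model@map), numeric(1))
      qs[[i]] <- c(qs[[i]], qv[-1])
      pe[i] <- run$potential[length(run$potential)]
    }
    # alternate even/odd neighbour swap attempts
    start <- if (ch %% 2L == 0L) 2L else 1L
    for (i in seq(start, nrep - 1L, by = 2L)) {
      att <- att + 1L
      dBeta <- 1 / temperatures[i] - 1 / temperatures[i + 1L]
      if (log(runif(1)) < dBeta * (pe[i] - pe[i + 1L])) {
        acc <- acc + 1L
        tmp <- x[[i]]; x[[i]] <- x[[i + 1L]]; x[[i + 1L]] <- tmp
        # rescale velocities to the new temperature
        sc <- sqrt(temperatures[i] / temperatures[i + 1L])
        tmpv <- v[[i]]
        v[[i]] <- v[[i + 1L]] * sc
        v[[i + 1L]] <- tmpv / sc
        tmpp <- pe[i]; pe[i] <- pe[i + 1L]; pe[i + 1L] <- tmpp
      }
    }
  }
  out <- lapply(qs, function(q) matrix(q, nrow = 1))
  out$swapAcceptance <- if (att) acc / att else NA_real_
  out
}

#' Perturb-and-relax protocol
#'
#' Stage 1 steers the distance between a residue pair from its native value
#' to native + `displacement` via a moving harmonic restraint; stage 2
#' removes all restraints and records the relaxation.  The Q(t) series of
#' stage 2 feeds [qAutocorrelation()] and [fitDoubleExponential()] for
#' relaxation-time extraction.
#'
#' @inheritParams runLangevin
#' @param residuePair integer pair `c(i, j)`; must not be bonded neighbours.
#' @param displacement distance increase in nm (default 1.5, i.e. 15 A).
#' @param strandRanges optional list of integer vectors (residue ranges of
#'   beta strands); pairs within one strand are rejected.
#' @param kRestraint restraint stiffness (default 500).
#' @param rampSteps stage-1 steps over which the target distance ramps.
#' @param nSteps stage-2 (relaxation) steps.
#' @return A [Trajectory-class] of the relaxation stage; metadata records
#'   the perturbed pair and the stage-1 endpoint.
#' @export
perturbAndRelax <- function(model, residuePair, thermostat, nSteps,
                            displacement = 1.5, strandRanges = NULL,
                            kRestraint = 500, rampSteps = 5000L,
                            reportEvery = 100L) {
  n <- nrow(model@structure@atoms)
  i <- residuePair[1]; j <- residuePair[2]
  stopifnot(i >= 1, j >= 1, i <= n, j <= n)
  if (abs(i - j) <= 1) stop("residue pair must not be bonded neighbours")
  if (!is.null(strandRanges)) {
    same <- any(vapply(strandRanges, function(rg) i %in% rg && j %in% rg,
                       logical(1)))
    if (same) stop("residues ", i, " and ", j, " lie on the same strand")
  }
  mc <- .model_cpp(model)
  stage1 <- .go_dynamics(mc, .num_mat(coords(model@structure), 3), NULL,
                         thermostat$timeStep, thermostat$gamma,
                         thermostat$temperature,
                         as.integer(rampSteps + 2000L),
                         as.integer(reportEvery),
                         as.numeric(thermostat$seed),
                         NULL,
                         list(i = as.integer(i), j = as.integer(j),
                              k_r = kRestraint, displacement = displacement,
                              ramp_steps = as.integer(rampSteps)))
  stage2 <- .go_dynamics(mc, stage1$x_final, stage1$v_final,
                         thermostat$timeStep, thermostat$gamma,
                         thermostat$temperature, as.integer(nSteps),
                         as.integer(reportEvery),
                         as.numeric(thermostat$seed) + 0.5 * 2^31,
                         NULL, NULL)
  .traj_from_run(stage2, runId = sprintf("relax-%d-%d", i, j),
                 metadata = list(kind = "relax", pair = c(i, j),
                                 displacement = displacement,
                                 thermostat = thermostat,
                                 perturbedEndpoint = stage1$x_final))
}

#' Default perturbation pair list
#'
#' The residue pairs pulled apart by 15 A in the relaxation-time protocol
#' for a 110-residue loop-truncated superoxide dismutase monomer: 13-69,
#' 20-80, 35-45, 60-25 and 95-102 (one residue drawn from each beta
#' strand, pair members never on the same strand).  For shorter chains the pairs are scaled proportionally and
#' clamped to valid indices.
#'
#' @param nResidues chain length.
#' @return A list of integer pairs.
#' @export
defaultPerturbationPairs <- function(nResidues = 110L) {
  base <- list(c(13L, 69L), c(20L, 80L), c(35L, 45L), c(60L, 25L), c(95L, 102L))
  if (nResidues == 110L) return(base)
  lapply(base, function(p) {
    q <- pmax(1L, pmin(nResidues, as.integer(round(p * nResidues / 110))))
    if (abs(q[1] - q[2]) <= 1) q[2] <- min(nResidues, q[1] + 2L)
    q
  })
}
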