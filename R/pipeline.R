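# End-to-end orchestration: generate -> simulate -> calibrate -> pull ->
# analyze -> taxonomy, from a single validated config.

# display-only conversion between the reduced temperature unit and kelvin,
# calibrated so the default toy model's folding temperature (~1.36 reduced)
# maps near 158 K
.KELVIN_PER_REDUCED <- 116

#' Convert a reduced temperature to kelvin for display
#' @param temperature reduced temperature.
#' @param kelvinPerReduced conversion constant (K per reduced unit).
#' @return Temperature in kelvin.
#' @export
reducedToKelvin <- function(temperature, kelvinPerReduced = .KELVIN_PER_REDUCED)
  temperature * kelvinPerReduced

.default_config <- function() list(
  structure = list(motif = "hairpin-barrel", nResidues = 40L, seed = 1L,
                   pdb = NULL, chain = "A"),
  resolution = "ca",
  contacts = list(model = "ca"),         # Table-style presets by model tag
  temperatures = seq(0.7, 1.6, by = 0.1),
  meltSteps = 200000L, meltRuns = 1L,
  relaxSteps = 40000L,
  pulls = 20L,
  protocol = list(k = 837, v = 0.02, L = NULL),
  timeStep = 0.004, timeConstant = 12,
  seed = 1L,
  outputDir = NULL)

#' Validate a pipeline configuration
#'
#' Reads a YAML (or JSON) config, applies defaults, and reports every
#' problem at once.  Unknown keys are rejected; duplicate seeds warn but do
#' not fail.
#'
#' @param config path to a YAML/JSON file, or a named list.
#' @return The validated, default-filled config list.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    config <- tryCatch(yaml::read_yaml(config),
                       error = function(e) jsonlite::fromJSON(config,
                                                              simplifyVector = TRUE))
  }
  def <- .default_config()
  unknown <- setdiff(names(config), names(def))
  errs <- character()
  if (length(unknown))
    errs <- c(errs, paste("unknown config keys:", paste(unknown, collapse = ", ")))
  merged <- utils::modifyList(def, config[intersect(names(config), names(def))])
  if (!is.null(merged$structure$pdb) && !file.exists(merged$structure$pdb))
    errs <- c(errs, paste("structure file not found:", merged$structure$pdb))
  if (any(merged$temperatures <= 0))
    errs <- c(errs, "temperatures must be positive")
  if (merged$pulls < 1) errs <- c(errs, "number of pulling runs must be >= 1")
  if (merged$protocol$k <= 0 || merged$protocol$v <= 0)
    errs <- c(errs, "protocol spring constant and speed must be positive")
  if (merged$timeStep <= 0) errs <- c(errs, "time step must be positive")
  if (length(errs)) stop(paste(errs, collapse = "; "))
  seeds <- merged$seed + seq_len(merged$pulls)
  if (anyDuplicated(seeds)) warning("duplicate pulling seeds")
  merged
}

#' Run the full pipeline
#'
#' Executes, in order: structure generation (or PDB read), contact-map and
#' Go-model construction, a melting scan with two-state fit, the
#' perturb-and-relax relaxation-rate protocol, constant-velocity pulls at
#' 0.9 Tf, work/Jarzynski analysis, and the pathway taxonomy.  Outputs are
#' written under `outputDir` in a fixed layout (`melting/`, `relaxation/`,
#' `pulls/`, `analysis/`) with a manifest JSON recording the seeds and every
#' derived constant (Tf, Tsim, relaxation time, Jarzynski dG, cluster
#' counts); stage failures are recorded in the manifest and downstream
#' stages are skipped.
#'
#' @param config config list or path (see [validateConfig()]).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  out <- cfg$outputDir
  if (!is.null(out)) {
    for (d in c("", "melting", "relaxation", "pulls", "analysis"))
      dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  manifest <- list(config = cfg, stages = list(), constants = list())
  res <- list()
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(e))
    warning("stage '", stage, "' failed: ", conditionMessage(e))
    NULL
  }
  done <- function(stage) manifest$stages[[stage]] <<- list(status = "ok")

  # 1. structure
  res$structure <- tryCatch({
    s <- if (!is.null(cfg$structure$pdb)) {
      coarseGrain(readStructure(cfg$structure$pdb, cfg$structure$chain), "Ca")
    } else {
      generateToyStructure(cfg$structure$nResidues, cfg$structure$motif,
                           seed = cfg$structure$seed)
    }
    done("structure"); s
  }, error = function(e) fail("structure", e))
  if (is.null(res$structure)) return(invisible(list(manifest = manifest)))

  # 2. contacts + model
  res$map <- tryCatch({
    m <- buildNativeContactMap(res$structure,
                               contactDefinition(cfg$contacts$model))
    done("contacts"); m
  }, error = function(e) fail("contacts", e))
  res$model <- tryCatch({
    m <- buildCaGoModel(res$structure)
    done("model"); m
  }, error = function(e) fail("model", e))
  if (is.null(res$map) || is.null(res$model))
    return(invisible(c(res, list(manifest = manifest))))

  # 3. melting scan + two-state fit (reduced units: R = 1)
  res$melting <- tryCatch({
    curve <- runTemperatureScan(res$model, cfg$temperatures, cfg$meltSteps,
                                nRuns = cfg$meltRuns, seed = cfg$seed)
    fit <- fitTwoState(curve, R = 1)
    if (!is.null(out)) {
      write.csv(data.frame(temperature = curve@temperatures,
                           meanQ = curve@meanQ, semQ = curve@semQ),
                file.path(out, "melting", "melting_curve.csv"),
                row.names = FALSE)
    }
    manifest$constants$Tf <- fit@Tf
    manifest$constants$Tf_kelvin <- reducedToKelvin(fit@Tf)
    manifest$constants$Tsim <- 0.9 * fit@Tf
    done("melting")
    list(curve = curve, fit = fit)
  }, error = function(e) fail("melting", e))
  Tsim <- if (!is.null(res$melting)) 0.9 * res$melting$fit@Tf else NULL

  # 4. relaxation rates
  res$relaxation <- tryCatch({
    if (is.null(Tsim)) stop("no simulation temperature (melting stage failed)")
    pairs <- defaultPerturbationPairs(nResidues(res$structure))
    k1s <- c()
    for (pi in seq_along(pairs)) {
      th <- thermostatSettings(Tsim, cfg$timeConstant, cfg$timeStep,
                               seed = cfg$seed + 100L + pi)
      traj <- perturbAndRelax(res$model, pairs[[pi]], th, cfg$relaxSteps)
      qs <- trajectoryQ(traj, res$map)
      acfd <- qAutocorrelation(qs)
      acfd$lag <- acfd$lag * (traj@time[2] - traj@time[1])
      rf <- fitDoubleExponential(acfd)
      k1s <- c(k1s, rf@kappa1)
      if (!is.null(out))
        write.csv(data.frame(time = traj@time, Q = qs),
                  file.path(out, "relaxation",
                            sprintf("relax_%d_%d.csv", pairs[[pi]][1],
                                    pairs[[pi]][2])),
                  row.names = FALSE)
    }
    tModel <- 1 / mean(k1s)
    manifest$constants$kappa1 <- mean(k1s)
    manifest$constants$tModel <- tModel
    done("relaxation")
    list(kappa1 = k1s, tModel = tModel)
  }, error = function(e) fail("relaxation", e))

  # 5. pulls at 0.9 Tf
  res$pulls <- tryCatch({
    if (is.null(Tsim)) stop("no simulation temperature (melting stage failed)")
    trajs <- list()
    for (r in seq_len(cfg$pulls)) {
      th <- thermostatSettings(Tsim, cfg$timeConstant, cfg$timeStep,
                               seed = cfg$seed + r)
      proto <- pullingProtocol(k = cfg$protocol$k, v = cfg$protocol$v,
                               L = cfg$protocol$L)
      traj <- runPull(res$model, proto, th)
      traj@runId <- sprintf("pull-%02d", r)
      trajs[[r]] <- traj
      if (!is.null(out))
        write.csv(data.frame(time = traj@time, extension = traj@extension,
                             force = traj@force,
                             Q = trajectoryQ(traj, res$map)),
                  file.path(out, "pulls", sprintf("pull_%02d.csv", r)),
                  row.names = FALSE)
    }
    done("pulls"); trajs
  }, error = function(e) fail("pulls", e))

  # 6. work + Jarzynski
  res$work <- tryCatch({
    if (is.null(res$pulls)) stop("no pulling trajectories")
    L <- res$pulls[[1]]@metadata$L
    works <- vapply(res$pulls, function(tr)
      pullingWork(tr@extension, tr@force, L), numeric(1))
    we <- workEnsemble(works, beta = 1 / Tsim, L = L)
    dG <- jarzynskiFreeEnergy(we)
    manifest$constants$meanWork <- mean(works)
    manifest$constants$jarzynskiDG <- dG
    done("work")
    list(ensemble = we, dG = dG)
  }, error = function(e) fail("work", e))

  # 7. taxonomy
  res$taxonomy <- tryCatch({
    if (is.null(res$pulls)) stop("no pulling trajectories")
    qLevels <- c(0.8, 0.6, 0.4, 0.2)
    prof <- residueProfile(res$pulls, res$map, dQ = 0.05)
    bins <- as.numeric(colnames(prof))
    sets <- list()
    for (q in qLevels) {
      fr <- framesAtQ(res$pulls, res$map, q, tol = 0.08)
      if (length(fr) < 2) next
      seg <- foldedSegment(prof[, which.min(abs(bins - q))])
      if (is.na(seg$start) || seg$end - seg$start + 1 < 3) next
      sets[[length(sets) + 1L]] <- clusterByTM(allVsAllTM(fr, seg), Q = q)
    }
    if (length(sets) < 2) stop("too few populated Q levels for a graph")
    graph <- pathwayGraph(sets)
    dom <- dominantPathway(graph)
    manifest$constants$nQLevels <- length(sets)
    manifest$constants$dominantFlow <- dom$flow
    if (!is.null(out)) {
      jsonlite::write_json(
        list(nodes = graph@nodes, edges = graph@edges,
             dominant = dom$clusters, flow = dom$flow),
        file.path(out, "analysis", "pathway_graph.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    done("taxonomy")
    list(graph = graph, dominant = dom)
  }, error = function(e) fail("taxonomy", e))

  if (!is.null(out)) {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(c(res, list(manifest = manifest)))
}
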