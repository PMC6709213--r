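#' Default pipeline configuration
#'
#' Nested list of settings for [runPipeline()], grouped in blocks:
#' `geometry` (viewer and grid), `simulation` (subjects, runs, voxels,
#' noise, seed), `iem` (basis, pixel grid, stimulus profile, mirroring),
#' `fitting` (search grid), `decoding` (classifier cost, permutation
#' iterations, FDR levels) and `stats` (bootstrap iterations, CI level).
#' Any block may be partially overridden; unknown keys are rejected by
#' [validatePipelineConfig()].
#'
#' @return the configuration list.
#' @export
defaultPipelineConfig <- function() {
  list(
    geometry = list(
      eye_offset = 0.4, fixation_distance = 10,
      vertical_fov = 25, horizontal_fov = 33,
      z_rows = c(-1.5, -0.9, -0.3, 0.3, 0.9, 1.5),
      ecc_range = c(0.9, 9.8)),
    simulation = list(
      n_subjects = 9L, n_runs = 26L, n_voxels = 60L,
      noise = list(type = "relative", sd = 2.5),
      n_null = 9L, mirror_runs = "even",
      weight_distribution = "halfnormal", seed = 1L),
    iem = list(
      n_channels = 6L, basis_centers = seq(-1.5, 1.5, length.out = 6),
      basis_size = 1.8, pixel_range = c(-2.75, 2.75), n_pixels = 111L,
      profile_mode = "delta", profile_extent = NULL),
    fitting = list(
      center_range = c(-2.75, 2.75), center_step = 0.1,
      size_range = c(1.5, 15), size_step = 0.1,
      baseline_bounds = c(-5, 5), refine_box = 0.1),
    decoding = list(cost = 1, n_perm = 0L, q_levels = c(0.05, 0.01)),
    stats = list(n_boot = 1000L, ci_level = 0.95))
}

#' Read a pipeline configuration from YAML
#'
#' Loads a YAML file and merges it over [defaultPipelineConfig()] (given
#' keys override defaults; omitted keys keep their default).
#'
#' @param path YAML file path.
#' @return a validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultPipelineConfig()
  for (block in names(user)) {
    if (!block %in% names(cfg)) {
      cfg[[block]] <- user[[block]]
    } else {
      for (key in names(user[[block]])) cfg[[block]][[key]] <- user[[block]][[key]]
    }
  }
  validatePipelineConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks block and key presence and the cross-cutting constraints (at
#' least two runs for cross-validation, positive counts, known modes), and
#' stops with a message listing every offending key before any computation
#' is attempted.
#'
#' @param config a configuration list.
#' @return `TRUE` invisibly if valid.
#' @export
validatePipelineConfig <- function(config) {
  bad <- character()
  need <- names(defaultPipelineConfig())
  missBlocks <- setdiff(need, names(config))
  if (length(missBlocks))
    bad <- c(bad, paste("missing block(s):", paste(missBlocks, collapse = ", ")))
  unknown <- setdiff(names(config), need)
  if (length(unknown))
    bad <- c(bad, paste("unknown block(s):", paste(unknown, collapse = ", ")))
  sim <- config$simulation
  if (!is.null(sim)) {
    if ((sim$n_runs %||% 0) < 2)
      bad <- c(bad, "simulation$n_runs must be >= 2 (leave-one-run-out cross-validation needs at least two runs)")
    if ((sim$n_subjects %||% 0) < 1) bad <- c(bad, "simulation$n_subjects must be >= 1")
    if ((sim$n_voxels %||% 0) < 6)
      bad <- c(bad, "simulation$n_voxels must be >= the number of channels")
    if (is.null(sim$seed)) bad <- c(bad, "simulation$seed must be set explicitly")
    if (!is.null(sim$mirror_runs) && !sim$mirror_runs %in% c("even", "odd"))
      bad <- c(bad, "simulation$mirror_runs must be \"even\" or \"odd\"")
  }
  iem <- config$iem
  if (!is.null(iem)) {
    if (length(iem$basis_centers %||% numeric()) != (iem$n_channels %||% -1))
      bad <- c(bad, "iem$basis_centers must have iem$n_channels entries")
    if (!is.null(iem$profile_mode) && !iem$profile_mode %in% c("delta", "boxcar"))
      bad <- c(bad, "iem$profile_mode must be \"delta\" or \"boxcar\"")
  }
  dec <- config$decoding
  if (!is.null(dec) && (dec$n_perm %||% 0) < 0)
    bad <- c(bad, "decoding$n_perm must be >= 0")
  if (length(bad))
    stop("invalid pipeline configuration:\n  - ", paste(bad, collapse = "\n  - "),
      call. = FALSE)
  invisible(TRUE)
}

pipelineGeom <- function(cfg) {
  ViewerGeometry(eyeOffset = cfg$geometry$eye_offset,
    fixationDistance = cfg$geometry$fixation_distance,
    verticalFov = cfg$geometry$vertical_fov,
    horizontalFov = cfg$geometry$horizontal_fov)
}

pipelineBasis <- function(cfg) {
  px <- PixelGrid(cfg$iem$pixel_range[1], cfg$iem$pixel_range[2],
    cfg$iem$n_pixels)
  buildBasis(cfg$iem$n_channels, px, cfg$iem$basis_centers,
    cfg$iem$basis_size)
}

pipelineFitSpec <- function(cfg) {
  fitGridSpec(cfg$fitting$center_range, cfg$fitting$center_step,
    cfg$fitting$size_range, cfg$fitting$size_step,
    cfg$fitting$baseline_bounds, cfg$fitting$refine_box)
}

#' Run the simulation-to-statistics pipeline
#'
#' Orchestrates the full analysis: simulate a multi-subject experiment,
#' reconstruct per-axis position representations with the cross-validated
#' inverted encoding model, fit every averaged representation, decode all
#' depth-row pairs, and compute group statistics (bootstrap center-vs-true
#' slopes and d-prime/disparity slopes). Identical configurations produce
#' identical numeric outputs.
#'
#' Stages can be run separately by passing a previous `bundle`: each stage
#' reads only what earlier stages produced, so
#' `runPipeline(cfg, stages = "simulate")` piped into
#' `runPipeline(cfg, stages = c("iem", "fit"), bundle = .)` equals a
#' single-shot run.
#'
#' @param config configuration list (see [defaultPipelineConfig()]).
#' @param outDir optional output directory; when given, all tables are
#'   written as CSV together with the configuration and a manifest.
#' @param stages which stages to run, in order; subset of
#'   `c("simulate", "iem", "fit", "decode", "stats")`.
#' @param bundle partial result bundle from earlier stages.
#' @param verbose log stage boundaries and shapes.
#' @return the result bundle: a list with elements `config`, `experiment`,
#'   `recon` (per axis/subject averaged reconstructions), `fits`,
#'   `decoding`, `decodeGroup`, `group`, and (when written) `outDir`.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir = NULL,
                        stages = c("simulate", "iem", "fit", "decode", "stats"),
                        bundle = NULL, verbose = FALSE) {
  validatePipelineConfig(config)
  stages <- match.arg(stages, several.ok = TRUE)
  bundle <- bundle %||% list()
  bundle$config <- config
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stamp <- function(stage) {
    say("[%s] done at %.1f s", stage, proc.time()[["elapsed"]] - t0)
  }

  if ("simulate" %in% stages) {
    cfgS <- config$simulation
    bundle$experiment <- simulateExperiment(
      nSubjects = cfgS$n_subjects, nRuns = cfgS$n_runs,
      nVoxels = cfgS$n_voxels, noise = cfgS$noise, nNull = cfgS$n_null,
      mirrorRuns = cfgS$mirror_runs, geom = pipelineGeom(config),
      weightDistribution = cfgS$weight_distribution, seed = cfgS$seed)
    stamp("simulate")
  }

  if ("iem" %in% stages) {
    exp <- bundle$experiment %||% stop("iem stage needs a simulated experiment")
    basis <- pipelineBasis(config)
    bundle$basis <- basis
    bundle$recon <- lapply(c(x = "x", z = "z"), function(ax) {
      lapply(seq_len(nSubjects(exp)), function(s) {
        averageByPosition(crossvalReconstruct(subjectData(exp, s), basis,
          axis = ax, profileMode = config$iem$profile_mode,
          extent = config$iem$profile_extent))
      })
    })
    stamp("iem")
  }

  if ("fit" %in% stages) {
    recon <- bundle$recon %||% stop("fit stage needs reconstructions")
    spec <- pipelineFitSpec(config)
    pre <- precomputeFitGrid(recon[[1]][[1]]@pixels, spec)
    fits <- do.call(rbind, lapply(names(recon), function(ax) {
      do.call(rbind, lapply(seq_along(recon[[ax]]), function(s) {
        cbind(subject = s, fitReconstruction(recon[[ax]][[s]], spec, pre))
      }))
    }))
    rownames(fits) <- NULL
    bundle$fits <- fits
    stamp("fit")
  }

  if ("decode" %in% stages) {
    exp <- bundle$experiment %||% stop("decode stage needs a simulated experiment")
    scheme <- pairwiseScheme()
    dec <- do.call(rbind, lapply(seq_len(nSubjects(exp)), function(s) {
      cbind(subject = s, sixWayDecode(subjectData(exp, s), scheme,
        cost = config$decoding$cost))
    }))
    rownames(dec) <- NULL
    bundle$decoding <- dec
    dMat <- matrix(dec$dprime, nrow = nSubjects(exp), byrow = TRUE)
    slope <- dprimeDisparitySlope(dMat, scheme$delta_disparity_arcmin,
      nBoot = config$stats$n_boot, seed = childSeed(config$simulation$seed, 91L))
    group <- list(meanDprime = colMeans(dMat), sixWay = mean(dMat),
      slope = slope)
    if ((config$decoding$n_perm %||% 0) > 0) {
      nulls <- lapply(seq_len(nrow(scheme)), function(k) {
        t(vapply(seq_len(nSubjects(exp)), function(s)
          permutationNull(subjectData(exp, s), scheme$pair_i[k],
            scheme$pair_j[k], nIter = config$decoding$n_perm,
            seed = childSeed(config$simulation$seed, 17L, s, k),
            cost = config$decoding$cost),
          numeric(config$decoding$n_perm)))
      })
      pPerm <- vapply(seq_len(nrow(scheme)), function(k)
        groupPermutationPvalue(dMat[, k], nulls[[k]]), 0)
      group$pPerm <- pPerm
      for (q in config$decoding$q_levels)
        group[[sprintf("fdr_reject_%02d", round(q * 100))]] <- fdrBh(pPerm, q)
    }
    bundle$decodeGroup <- group
    stamp("decode")
  }

  if ("stats" %in% stages) {
    fits <- bundle$fits %||% stop("stats stage needs fit tables")
    nSub <- max(fits$subject)
    rows <- list()
    for (ax in unique(fits$axis)) {
      f <- fits[fits$axis == ax, ]
      centers <- matrix(NA_real_, nSub, 6)
      for (s in seq_len(nSub))
        centers[s, ] <- f$center[f$subject == s][order(f$position[f$subject == s])]
      truth <- f$true_coord[f$subject == 1][order(f$position[f$subject == 1])]
      sl <- bootstrapCenterSlope(centers, truth,
        nIter = config$stats$n_boot, level = config$stats$ci_level,
        seed = childSeed(config$simulation$seed, 23L, match(ax, c("x", "z"))))
      bundle[[paste0("slope_", ax)]] <- sl
      rows[[paste0(ax, "_slope")]] <- data.frame(axis = ax, metric = "slope",
        estimate = bootPoint(sl)[["slope"]], ci_lo = sl@ciLower[1],
        ci_hi = sl@ciUpper[1], p = distributionPvalueVsZero(sl))
      for (metric in c("center_error", "amplitude", "size", "baseline")) {
        col <- if (metric == "center_error") "center_error" else metric
        perSub <- vapply(seq_len(nSub), function(s)
          mean(f[[col]][f$subject == s]), 0)
        bs <- bootstrapSubjects(perSub, nIter = config$stats$n_boot,
          level = config$stats$ci_level,
          seed = childSeed(config$simulation$seed, 29L,
            match(ax, c("x", "z")), match(metric,
              c("center_error", "amplitude", "size", "baseline"))))
        rows[[paste0(ax, "_", metric)]] <- data.frame(axis = ax,
          metric = metric, estimate = unname(bootPoint(bs)),
          ci_lo = bs@ciLower[1], ci_hi = bs@ciUpper[1], p = NA_real_)
      }
    }
    group <- do.call(rbind, rows)
    rownames(group) <- NULL
    bundle$group <- group
    stamp("stats")
  }

  if (!is.null(outDir)) {
    writePipelineOutputs(bundle, outDir)
    bundle$outDir <- outDir
  }
  bundle
}

# write all bundle tables plus config + manifest
writePipelineOutputs <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(outDir, name)
  cfgPath <- out("config.yaml")
  yaml::write_yaml(bundle$config, cfgPath)
  if (!is.null(bundle$experiment)) {
    exp <- bundle$experiment
    exportGrid(exp@gridBase, out("grid.csv"))
    for (s in seq_len(nSubjects(exp))) {
      te <- subjectData(exp, s)
      tab <- cbind(subject = s, trialInfo(te),
        as.data.frame(t(trialResponses(te))))
      write.csv(tab, out(sprintf("trials_s%02d.csv", s)), row.names = FALSE)
    }
  }
  if (!is.null(bundle$recon)) {
    for (ax in names(bundle$recon)) {
      tab <- do.call(rbind, lapply(seq_along(bundle$recon[[ax]]), function(s) {
        r <- bundle$recon[[ax]][[s]]
        cbind(subject = s, reconInfo(r),
          as.data.frame(reconCurves(r),
            col.names = paste0("px_", seq_len(ncol(reconCurves(r))))))
      }))
      write.csv(tab, out(sprintf("recon_%s.csv", ax)), row.names = FALSE)
    }
  }
  if (!is.null(bundle$fits))
    write.csv(bundle$fits, out("fits.csv"), row.names = FALSE)
  if (!is.null(bundle$decoding))
    write.csv(bundle$decoding, out("decoding.csv"), row.names = FALSE)
  if (!is.null(bundle$group))
    write.csv(bundle$group, out("group_summary.csv"), row.names = FALSE)
  manifest <- list(
    package = "depthIEM",
    version = as.character(utils::packageVersion("depthIEM")),
    config_md5 = unname(tools::md5sum(cfgPath)),
    seed = bundle$config$simulation$seed,
    tables = list.files(outDir, pattern = "\\.csv$"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
    pretty = TRUE)
  invisible(outDir)
}
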