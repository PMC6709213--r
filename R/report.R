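#' Summarize a pipeline result bundle
#'
#' Produces a human-readable text summary of the bundle's available
#' sections (six-way decoding, d-prime/disparity slope, representation
#' fits, center-vs-true slopes) and, optionally, diagnostic figures:
#' per-axis mean reconstructions with true-position markers, fitted-center
#' versus true-position scatter with the regression line, and d-prime
#' against disparity difference. Missing sections are skipped with a
#' warning.
#'
#' @param bundle a result bundle from [runPipeline()].
#' @param file optional path to also write the text summary to.
#' @param plots logical; write figures (requires the `ggplot2` package).
#' @param plotDir directory for figures (defaults to `bundle$outDir`).
#' @return the summary lines, invisibly.
#' @export
pipelineReport <- function(bundle, file = NULL, plots = FALSE,
                           plotDir = NULL) {
  lines <- c("depthIEM pipeline report", strrep("=", 24))
  if (!is.null(bundle$experiment)) {
    exp <- bundle$experiment
    te <- subjectData(exp, 1)
    lines <- c(lines, sprintf(
      "Simulation: %d subjects, %d runs, %d voxels, seed %d",
      nSubjects(exp), length(unique(trialInfo(te)$run)), nrow(te), exp@seed))
  }
  if (!is.null(bundle$decodeGroup)) {
    g <- bundle$decodeGroup
    lines <- c(lines,
      sprintf("Six-way decoding: mean d' = %.3f", g$sixWay),
      sprintf("d'/disparity slope: %.4f per arcmin [%.4f, %.4f], p(t) = %.3g",
        g$slope$slope, g$slope$ci[1], g$slope$ci[2], g$slope$pTTest))
  } else {
    warning("no decoding results in the bundle; section omitted")
  }
  if (!is.null(bundle$group)) {
    for (ax in unique(bundle$group$axis)) {
      sl <- bundle$group[bundle$group$axis == ax &
        bundle$group$metric == "slope", ]
      er <- bundle$group[bundle$group$axis == ax &
        bundle$group$metric == "center_error", ]
      lines <- c(lines, sprintf(
        "%s axis: center-vs-true slope %.3f [%.3f, %.3f] (p = %.3g), mean |center error| %.3f",
        ax, sl$estimate, sl$ci_lo, sl$ci_hi, sl$p, er$estimate))
    }
  } else {
    warning("no group statistics in the bundle; section omitted")
  }
  if (plots) {
    dir <- plotDir %||% bundle$outDir
    if (is.null(dir)) {
      warning("no plot directory available; figures not written")
    } else if (!requireNamespace("ggplot2", quietly = TRUE)) {
      warning("ggplot2 not installed; figures not written")
    } else {
      writeReportPlots(bundle, dir)
      lines <- c(lines, sprintf("Figures written to %s", dir))
    }
  }
  txt <- paste(lines, collapse = "\n")
  cat(txt, "\n")
  if (!is.null(file)) writeLines(txt, file)
  invisible(lines)
}

writeReportPlots <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes
  if (!is.null(bundle$recon)) {
    for (ax in names(bundle$recon)) {
      rs <- bundle$recon[[ax]]
      px <- pixelCoords(rs[[1]])
      mean_curves <- Reduce(`+`, lapply(rs, reconCurves)) / length(rs)
      info <- reconInfo(rs[[1]])
      df <- do.call(rbind, lapply(seq_len(nrow(mean_curves)), function(i)
        data.frame(pixel = px, value = mean_curves[i, ],
          position = factor(info$true_coord[i]))))
      p <- gg(df, aes(pixel, value, color = position)) +
        ggplot2::geom_line() +
        ggplot2::geom_vline(
          xintercept = info$true_coord, linetype = "dashed", alpha = 0.4) +
        ggplot2::labs(x = paste(ax, "(scene units)"),
          y = "representation", title = paste("Mean representations,", ax))
      ggplot2::ggsave(file.path(dir, sprintf("recon_%s.pdf", ax)), p,
        width = 6, height = 4)
    }
  }
  if (!is.null(bundle$fits)) {
    df <- bundle$fits
    p <- gg(df, aes(true_coord, center)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey") +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
      ggplot2::facet_wrap(~axis) +
      ggplot2::labs(x = "true position", y = "fitted center")
    ggplot2::ggsave(file.path(dir, "centers_vs_true.pdf"), p,
      width = 7, height = 4)
  }
  if (!is.null(bundle$decoding)) {
    df <- bundle$decoding
    p <- gg(df, aes(delta_disparity_arcmin, dprime)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
      ggplot2::labs(x = "disparity difference (arcmin)", y = "d'")
    ggplot2::ggsave(file.path(dir, "dprime_vs_disparity.pdf"), p,
      width = 6, height = 4)
  }
  invisible(dir)
}
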