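#' @describeIn TrapSeries study years
#' @param x object.
#' @export
setMethod("studyYears", "TrapSeries", function(x) x@years)

#' @describeIn CovariateSeries study years
#' @param x object.
#' @export
setMethod("studyYears", "CovariateSeries", function(x) x@years)

#' @describeIn LatentStates study years
#' @param x object.
#' @export
setMethod("studyYears", "LatentStates", function(x) x@years)

#' @describeIn TrapSeries number of years
#' @export
setMethod("nYears", "TrapSeries", function(x) length(x@years))

#' @describeIn CovariateSeries number of years
#' @export
setMethod("nYears", "CovariateSeries", function(x) length(x@years))

#' @describeIn LatentStates number of years
#' @export
setMethod("nYears", "LatentStates", function(x) length(x@years))

#' @describeIn TrapSeries the six-column count matrix
#' @export
setMethod("trapCounts", "TrapSeries", function(x) x@counts)

#' @describeIn TrapSeries two-day totals per demographic class
#' @export
setMethod("trapTotals", "TrapSeries", function(x) {
  cnt <- x@counts
  out <- cbind(adults_june = cnt[, 1] + cnt[, 2],
               juveniles_june = cnt[, 3] + cnt[, 4],
               adults_december = cnt[, 5] + cnt[, 6])
  rownames(out) <- as.character(x@years)
  out
})

#' @describeIn CovariateSeries raw covariates
#' @export
setMethod("rawCovariates", "CovariateSeries", function(x) x@raw)

#' @describeIn CovariateSeries standardized covariates
#' @export
setMethod("zCovariates", "CovariateSeries", function(x) x@z)

#' @describeIn CovariateSeries standardization constants
#' @export
setMethod("covariateScaling", "CovariateSeries", function(x) x@scaling)

#' @describeIn LatentStates June adult abundances
#' @export
setMethod("naJun", "LatentStates", function(x) x@naJun)

#' @describeIn LatentStates June juvenile abundances
#' @export
setMethod("nJuv", "LatentStates", function(x) x@nj)

#' @describeIn LatentStates December adult abundances
#' @export
setMethod("naDec", "LatentStates", function(x) x@naDec)

#' @describeIn PosteriorSummary parameter summary table
#' @param x object.
#' @export
setMethod("parameterTable", "PosteriorSummary", function(x) x@parameters)

#' @describeIn PosteriorSummary latent-state summary table
#' @export
setMethod("latentTable", "PosteriorSummary", function(x) x@latents)

#' @describeIn PosteriorSummary retained draws
#' @export
setMethod("posteriorDraws", "PosteriorSummary", function(x) x@draws)

#' @describeIn PosteriorSummary convergence flag
#' @export
setMethod("isConverged", "PosteriorSummary", function(x) x@converged)

setMethod("show", "TrapSeries", function(object) {
  cat(sprintf("TrapSeries: %d years (%s..%s)\n", length(object@years),
              if (length(object@years)) min(object@years) else "-",
              if (length(object@years)) max(object@years) else "-"))
  tot <- trapTotals(object)
  for (j in colnames(tot)) {
    v <- tot[, j]
    cat(sprintf("  %-16s total range %s..%s, %d missing year(s)\n", j,
                if (all(is.na(v))) "-" else min(v, na.rm = TRUE),
                if (all(is.na(v))) "-" else max(v, na.rm = TRUE),
                sum(is.na(v))))
  }
  invisible(NULL)
})

setMethod("show", "CovariateSeries", function(object) {
  cat(sprintf("CovariateSeries: %d years\n", length(object@years)))
  for (j in colnames(object@raw)) {
    v <- object@raw[, j]
    cat(sprintf("  %-8s %.2f..%.2f (mean %.2f, sd %.2f)\n", j,
                min(v, na.rm = TRUE), max(v, na.rm = TRUE),
                object@scaling["mean", j], object@scaling["sd", j]))
  }
  invisible(NULL)
})

setMethod("show", "LatentStates", function(object) {
  cat(sprintf("LatentStates: %d years\n", length(object@years)))
  cat(sprintf("  adults June:      median %s\n", median(object@naJun, na.rm = TRUE)))
  cat(sprintf("  juveniles June:   median %s\n", median(object@nj, na.rm = TRUE)))
  cat(sprintf("  adults December:  median %s\n", median(object@naDec, na.rm = TRUE)))
  invisible(NULL)
})

setMethod("show", "ProcessParams", function(object) {
  cat("ProcessParams (log-scale seasonal submodels)\n")
  lab <- c(wg = "winter growth", r = "reproduction", sg = "summer growth")
  for (s in SUBMODELS) {
    cat(sprintf("  %-14s alpha % .3f  beta [% .3f % .3f % .3f % .3f % .3f]  sigma %.3f\n",
                lab[s], object@alpha[s],
                object@beta[s, 1], object@beta[s, 2], object@beta[s, 3],
                object@beta[s, 4], object@beta[s, 5], object@sigma[s]))
  }
  invisible(NULL)
})

setMethod("show", "CaptureProbs", function(object) {
  cat(sprintf("CaptureProbs: adults June %.3f, juveniles %.3f, adults December %.3f\n",
              object@pAdultJune, object@pJuvenile, object@pAdultDecember))
  invisible(NULL)
})

setMethod("show", "CenteringConstants", function(object) {
  cat(sprintf("CenteringConstants: mean log(Na_dec) = %.4f, mean log(Na_jun + Nj) = %.4f\n",
              object@meanLogNaDec, object@meanLogNJunTotal))
  invisible(NULL)
})

setMethod("show", "PosteriorSummary", function(object) {
  p <- object@parameters
  cat(sprintf("PosteriorSummary: %d parameters, %d latent summaries\n",
              nrow(p), nrow(object@latents)))
  cat(sprintf("  max R-hat %.3f (threshold %.2f) -> %s\n",
              if (all(is.na(p$rhat))) NA_real_ else max(p$rhat, na.rm = TRUE),
              object@rhatThreshold,
              if (object@converged) "converged" else "NOT converged"))
  sig <- p$parameter[p$excludesZero %in% TRUE]
  if (length(sig))
    cat("  95% CrI excludes zero:", paste(sig, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf("ScenarioConfig: %d years, mast prob %.2f (%.1f..%.1f g/m2 vs baseline %.1f..%.1f)\n",
              object@nYears, object@mastProb,
              object@mastRange[1], object@mastRange[2],
              object@baselineRange[1], object@baselineRange[2]))
  cat(sprintf("  winter temperature: Normal(%.1f, %.1f) clipped to [%.1f, %.1f] degC\n",
              object@tempMean, object@tempSd,
              object@tempRange[1], object@tempRange[2]))
  cat(sprintf("  initial December abundance %d, seed %d\n",
              object@initAbundance, object@seed))
  invisible(NULL)
})
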