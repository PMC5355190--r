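#' Study years of a time-series object
#' @param x a TrapSeries, CovariateSeries or LatentStates object.
#' @return integer vector of years.
#' @export
setGeneric("studyYears", function(x) standardGeneric("studyYears"))

#' Number of study years
#' @param x a TrapSeries, CovariateSeries or LatentStates object.
#' @return integer scalar.
#' @export
setGeneric("nYears", function(x) standardGeneric("nYears"))

#' Two-occasion trap counts
#' @param x a TrapSeries.
#' @return integer matrix with six columns (occasions 1 and 2 for each of
#'   the three demographic classes).
#' @export
setGeneric("trapCounts", function(x) standardGeneric("trapCounts"))

#' Two-day trap totals (naive density index)
#'
#' Row-wise occasion-1 + occasion-2 totals per demographic class; the
#' classical density index used before model-based estimation.
#' @param x a TrapSeries.
#' @return integer matrix with columns adults_june, juveniles_june,
#'   adults_december.
#' @export
setGeneric("trapTotals", function(x) standardGeneric("trapTotals"))

#' Raw covariate values
#' @param x a CovariateSeries.
#' @return numeric matrix with columns ash_mar, ash_dec, temp.
#' @export
setGeneric("rawCovariates", function(x) standardGeneric("rawCovariates"))

#' Standardized covariate values
#' @param x a CovariateSeries.
#' @return numeric matrix of z-scores, columns ash_mar, ash_dec, temp.
#' @export
setGeneric("zCovariates", function(x) standardGeneric("zCovariates"))

#' Standardization constants
#' @param x a CovariateSeries.
#' @return numeric matrix (rows mean, sd) per covariate.
#' @export
setGeneric("covariateScaling", function(x) standardGeneric("covariateScaling"))

#' Latent abundance accessors
#' @param x a LatentStates.
#' @return integer vector per year.
#' @export
setGeneric("naJun", function(x) standardGeneric("naJun"))

#' @rdname naJun
#' @export
setGeneric("nJuv", function(x) standardGeneric("nJuv"))

#' @rdname naJun
#' @export
setGeneric("naDec", function(x) standardGeneric("naDec"))

#' Posterior parameter table
#' @param x a PosteriorSummary.
#' @return data.frame with median, 95% CrI bounds, excludes-zero flag and
#'   R-hat per parameter.
#' @export
setGeneric("parameterTable", function(x) standardGeneric("parameterTable"))

#' Posterior latent-state table
#' @param x a PosteriorSummary.
#' @return data.frame with per-state, per-year median and 95% CrI.
#' @export
setGeneric("latentTable", function(x) standardGeneric("latentTable"))

#' Posterior draws
#' @param x a PosteriorSummary.
#' @return a coda::mcmc.list of monitored parameters.
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))

#' Convergence flag
#' @param x a PosteriorSummary.
#' @return logical; TRUE when all reported R-hat values are at or below the
#'   stored threshold.
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
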