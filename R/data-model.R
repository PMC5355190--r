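#' Construct a TrapSeries
#'
#' @param years integer vector of study years (strictly increasing).
#' @param adults_june,juveniles_june,adults_december two-column matrices (or
#'   data.frames) of occasion-1 and occasion-2 counts, one row per year;
#'   `NA` marks a missing session.
#' @return a validated [TrapSeries-class] object. Years with gaps are
#'   permitted; a message flags them because the latent chain treats the
#'   series as consecutive years.
#' @export
TrapSeries <- function(years, adults_june, juveniles_june, adults_december) {
  as2col <- function(m, what) {
    m <- as.matrix(m)
    if (ncol(m) != 2L)
      stop(sprintf("%s must have two occasion columns", what))
    storage.mode(m) <- "integer"
    m
  }
  counts <- cbind(as2col(adults_june, "adults_june"),
                  as2col(juveniles_june, "juveniles_june"),
                  as2col(adults_december, "adults_december"))
  colnames(counts) <- TRAP_COLS
  rownames(counts) <- as.character(years)
  years <- as.integer(years)
  if (length(years) > 1L && any(diff(years) > 1L))
    message("TrapSeries: year gaps at ",
            paste(years[which(diff(years) > 1L)], collapse = ", "),
            " (kept, flagged)")
  new("TrapSeries", years = years, counts = counts)
}

#' Standardize a covariate series to z-scores
#'
#' Centers and scales to sample mean 0 and sample (n-1 denominator) standard
#' deviation 1 over non-missing entries, returning the constants for
#' back-transformation. Covariates are standardized so that coefficient
#' magnitudes are comparable across forcings.
#'
#' @param x numeric vector, possibly with `NA`.
#' @return list with `z` (same length as `x`), `mean` and `sd`.
#' @export
standardizeSeries <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) < 2L)
    stop("standardizeSeries: need at least 2 non-missing values")
  m <- mean(obs)
  s <- sd(obs)
  if (!is.finite(s) || s == 0)
    stop("standardizeSeries: constant series (sd = 0)")
  list(z = (x - m) / s, mean = m, sd = s)
}

#' Construct a CovariateSeries
#'
#' Standardizes each covariate against its own series (mean/sd over
#' non-missing years). Indexing convention: the row for year t holds the
#' September(t)--March(t+1) fruit-fall `ash_mar` and December(t)--March(t+1)
#' mean minimum temperature `temp` driving the December(t) -> June(t+1)
#' transition, and the September(t)--December(t) early fruit-fall `ash_dec`
#' driving June(t) -> December(t). Getting this off by one silently corrupts
#' every regression, hence the prominent documentation.
#'
#' @param years integer vector of index years t.
#' @param ash_mar,ash_dec,temp numeric vectors (g/m2, g/m2, degrees C).
#' @return a validated [CovariateSeries-class].
#' @export
CovariateSeries <- function(years, ash_mar, ash_dec, temp) {
  raw <- cbind(ash_mar = as.numeric(ash_mar),
               ash_dec = as.numeric(ash_dec),
               temp = as.numeric(temp))
  rownames(raw) <- as.character(years)
  zs <- apply(raw, 2, standardizeSeries, simplify = FALSE)
  z <- vapply(zs, `[[`, numeric(nrow(raw)), "z")
  dimnames(z) <- dimnames(raw)
  scaling <- rbind(mean = vapply(zs, `[[`, 0, "mean"),
                   sd = vapply(zs, `[[`, 0, "sd"))
  new("CovariateSeries", years = as.integer(years), raw = raw,
      z = z, scaling = scaling)
}

#' Construct a LatentStates object
#' @param years integer vector.
#' @param naJun,nj,naDec integer abundance vectors (June adults, June
#'   juveniles, December adults); `NA` where a state is undefined.
#' @return a validated [LatentStates-class].
#' @export
LatentStates <- function(years, naJun, nj, naDec) {
  new("LatentStates", years = as.integer(years),
      naJun = as.integer(round(naJun)), nj = as.integer(round(nj)),
      naDec = as.integer(round(naDec)))
}

.checkCountColumn <- function(v, col) {
  bad <- which(!is.na(v) & (v < 0 | v != round(v)))
  if (length(bad))
    stop(sprintf("invalid trap count in row %d, column '%s': %s",
                 bad[1], col, v[bad[1]]), call. = FALSE)
  as.integer(v)
}

#' Read a trap-count series from CSV
#'
#' Expects a UTF-8 comma-delimited file with a header row naming `year` and
#' the six count columns `adults_june_1`, `adults_june_2`,
#' `juveniles_june_1`, `juveniles_june_2`, `adults_december_1`,
#' `adults_december_2`. Blank cells are missing sessions; they are flagged,
#' never imputed.
#'
#' @param path file path.
#' @return a validated [TrapSeries-class].
#' @export
readTrapSeries <- function(path) {
  df <- utils::read.csv(path, strip.white = TRUE)
  names(df) <- trimws(names(df))
  need <- c("year", TRAP_COLS)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trap CSV is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("trap CSV has no data rows")
  for (col in TRAP_COLS) df[[col]] <- .checkCountColumn(df[[col]], col)
  TrapSeries(df$year,
             adults_june = df[, TRAP_COLS[1:2]],
             juveniles_june = df[, TRAP_COLS[3:4]],
             adults_december = df[, TRAP_COLS[5:6]])
}

#' Write a trap-count series to CSV
#' @param x a TrapSeries.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrapSeries <- function(x, path) {
  df <- data.frame(year = x@years, x@counts, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a covariate series from CSV
#'
#' Expects columns `year`, `ash_mar`, `ash_dec`, `temp` (raw scales);
#' standardization is applied on read so z-scores always reflect the file's
#' own years.
#'
#' @param path file path.
#' @return a validated [CovariateSeries-class].
#' @export
readCovariateSeries <- function(path) {
  df <- utils::read.csv(path, strip.white = TRUE)
  need <- c("year", "ash_mar", "ash_dec", "temp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("covariate CSV is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("covariate CSV has no data rows")
  CovariateSeries(df$year, df$ash_mar, df$ash_dec, df$temp)
}

#' Write a covariate series to CSV (raw scales)
#' @param x a CovariateSeries.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCovariateSeries <- function(x, path) {
  df <- data.frame(year = x@years, x@raw, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write latent states to CSV (truth files for synthetic data)
#' @param x a LatentStates.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLatentStates <- function(x, path) {
  df <- data.frame(year = x@years, na_jun = x@naJun, nj = x@nj,
                   na_dec = x@naDec)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read latent states from CSV
#' @param path file path with columns year, na_jun, nj, na_dec.
#' @return a validated [LatentStates-class].
#' @export
readLatentStates <- function(path) {
  df <- utils::read.csv(path, strip.white = TRUE)
  LatentStates(df$year, df$na_jun, df$nj, df$na_dec)
}
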