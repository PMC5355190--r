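#' Fruit-fall accounting: seed counts to areal dry mass
#'
#' Converts a seed count per square metre and a mean single-seed dry mass
#' in milligrams to an areal density of dry seed mass in g/m2. Masses are
#' handled in mg internally; results are conventionally reported at 2
#' decimal places.
#'
#' @param countPerM2 seeds per m2 (>= 0).
#' @param meanSeedMassMg mean dry mass per seed in mg (> 0).
#' @return dry seed mass in g/m2 (exactly linear in both arguments).
#' @examples
#' seedsToDensity(998, 26.6766)  # ~26.62 g/m2
#' @export
seedsToDensity <- function(countPerM2, meanSeedMassMg) {
  stopifnot(all(countPerM2 >= 0), all(meanSeedMassMg >= 0))
  countPerM2 * meanSeedMassMg / 1000
}

#' Areal density of an experimental fruit addition
#'
#' Edible dry seed mass per unit area provided by scattering a known total
#' fruit mass over an experimental grid: mass x edible ratio / area,
#' returned in g/m2. The edible ratio is the dried mass of
#' edible/unparasitized seed per unit total fruit mass.
#'
#' @param totalFruitMassKg total fruit mass scattered, kg (>= 0).
#' @param edibleRatio dimensionless in [0, 1].
#' @param areaM2 grid area in m2 (> 0).
#' @return edible dry seed density in g/m2.
#' @examples
#' additionDensity(60, 0.5092, 4500)  # 60 kg over 0.45 ha -> ~6.79 g/m2
#' @export
additionDensity <- function(totalFruitMassKg, edibleRatio, areaM2) {
  stopifnot(all(totalFruitMassKg >= 0), all(edibleRatio >= 0),
            all(edibleRatio <= 1), all(areaM2 > 0))
  totalFruitMassKg * 1000 * edibleRatio / areaM2
}

#' Aborted-seed percentage in a fruit sample
#'
#' @param nAborted number of fruits with aborted seeds.
#' @param nSampled number of fruits sampled (> 0).
#' @return percentage, 100 * nAborted / nSampled.
#' @examples
#' abortedFraction(2, 50)  # 4
#' @export
abortedFraction <- function(nAborted, nSampled) {
  stopifnot(all(nSampled > 0), all(nAborted >= 0),
            all(nAborted <= nSampled))
  100 * nAborted / nSampled
}
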