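#' Load a biometry table
#'
#' Reads a TSV with header `ga_weeks  ofd_mm  bpd_mm  od_mm` giving the
#' occipitofrontal diameter (OFD), biparietal diameter (BPD) and ocular
#' diameter (OD) in mm as a function of gestational age. With no argument
#' the bundled default table is used: synthetic smooth growth curves
#' anchored at OD(31) = 14 mm and OFD(31) = 96 mm, a stand-in for published
#' growth norms which users can replace with their own TSV.
#'
#' @param path optional path to a TSV; default uses the bundled table.
#' @return A \linkS4class{BiometryTable}.
#' @export
biometryTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "biometry_default.tsv",
                        package = "FetalScout", mustWork = TRUE)
  tb <- read.delim(path, header = TRUE)
  new("BiometryTable", table = tb)
}

#' Look up reference anatomy at a gestational age
#'
#' Linear interpolation between the bracketing table rows; exact at the row
#' points. Every size threshold of the pipeline derives from these three
#' diameters.
#'
#' @param table a \linkS4class{BiometryTable}.
#' @param ga gestational age in weeks, within `[14, 40]`.
#' @return Named numeric vector `c(ofd, bpd, od)` in mm.
#' @export
lookupBiometry <- function(table, ga) {
  stopifnot(is(table, "BiometryTable"))
  if (!is.finite(ga) || ga < 14 || ga > 40)
    stop(sprintf(
      "gestational age %.1f weeks is outside the supported 14-40 week window",
      ga))
  tb <- table@table
  vals <- vapply(c("ofd_mm", "bpd_mm", "od_mm"), function(cn)
    stats::approx(tb$ga_weeks, tb[[cn]], xout = ga)$y, numeric(1))
  names(vals) <- c("ofd", "bpd", "od")
  vals
}
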