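#' Temperature-humidity index
#'
#' Heat-stress indicator combining air temperature and relative humidity:
#' `THI = t - 0.31 (1 - rh) (t - 14.4)`.  At `t = 14.4` C the index equals
#' the temperature for any humidity; above it, dry air lowers the index.
#'
#' @param t temperature in degrees Celsius.
#' @param rh relative humidity as a fraction in `[0, 1]`; values in
#'   `(1, 100]` are taken to be percentages and divided by 100.
#' @return the index, same length as `t`.
#' @examples
#' compute_thi(23.1, 0.60)   # 22.02
#' compute_thi(14.4, 0.10)   # pivot: 14.4
#' @export
compute_thi <- function(t, rh) {
  if (any(rh > 1 & rh <= 100)) rh[rh > 1] <- rh[rh > 1] / 100
  if (any(rh < 0 | rh > 1)) stop("relative humidity outside [0, 1]")
  t - 0.31 * (1 - rh) * (t - 14.4)
}

#' Read a breed-level climate/geography table
#'
#' Expects one row per breed with columns `breed_id`, `N` (animals), `LAT`,
#' `LON`, `MINaT`, `MAXaT`, `MThm`, `ANT` (temperatures, C), `TW` (thermal
#' width, C), `TAR`, `MxR`, `MiR` (rainfall, mm), `HrA`, `HrMx`, `HrMi`
#' (relative humidity, %), `THI` and `CTY` (climate type: A arid, SA semi
#' arid, SD semi damp, D damp, VD very damp).  The packaged table
#' (`system.file("extdata", "table8_climate.csv", package = "adaptscan")`)
#' covers the 31 sheep breeds.
#'
#' Three internal-consistency checks are run and reported as warnings, never
#' errors, because the printed labels take precedence over derivable
#' quantities: `TW` against `MAXaT - MINaT` (tolerance `0.2`), `THI` against
#' [compute_thi()] (`0.05`), and `CTY` against the total-annual-rainfall
#' bands (A: 0-250 mm, SA: 250-500, SD: 500-1000, D: 1000-2000, VD: >2000).
#'
#' @param path CSV path.
#' @param warn emit consistency warnings (default TRUE).
#' @return a data frame of class `climate_table`, row names = breed ids,
#'   with attribute `checks` listing the rows that failed each check.
#' @export
read_climate_table <- function(path, warn = TRUE) {
  x <- utils::read.csv(path, check.names = FALSE)
  if (!"breed_id" %in% names(x)) stop("climate table lacks breed_id")
  num <- c("LAT", "LON", "MINaT", "MAXaT", "MThm", "ANT", "TW",
           "TAR", "MxR", "MiR", "HrA", "HrMx", "HrMi", "THI")
  miss <- setdiff(c(num, "CTY"), names(x))
  if (length(miss)) stop("climate table lacks column(s): ",
                         paste(miss, collapse = ", "))
  rownames(x) <- x$breed_id

  tw_bad <- x$breed_id[abs(x$TW - (x$MAXaT - x$MINaT)) > 0.2]
  thi_bad <- x$breed_id[abs(x$THI - compute_thi(x$MAXaT, x$HrA / 100)) > 0.05]
  cty_exp <- cut(x$TAR, c(-Inf, 250, 500, 1000, 2000, Inf),
                 labels = c("A", "SA", "SD", "D", "VD"))
  cty_bad <- x$breed_id[as.character(cty_exp) != as.character(x$CTY)]
  if (warn) {
    if (length(tw_bad))
      warning("TW inconsistent with MAXaT - MINaT for: ",
              paste(tw_bad, collapse = ", "), call. = FALSE)
    if (length(thi_bad))
      warning("THI not reproducible from MAXaT and HrA for: ",
              paste(thi_bad, collapse = ", "), call. = FALSE)
    if (length(cty_bad))
      warning("CTY label outside its rainfall band for: ",
              paste(cty_bad, collapse = ", "), call. = FALSE)
  }
  structure(x, class = c("climate_table", "data.frame"),
            checks = list(tw = tw_bad, thi = thi_bad, cty = cty_bad))
}

#' Numeric climate predictor matrix
#'
#' Drops identifier columns and the categorical climate type, returning the
#' matrix of numeric environmental/geographic predictors used by the
#' regression stages (the discrete `CTY` is never a predictor).
#'
#' @param climate a `climate_table` (or any data frame with the columns).
#' @param variables which predictors to keep; default the full set of 14.
#' @return numeric matrix, rows = breeds.
#' @export
climate_predictors <- function(climate,
                               variables = c("LAT", "LON", "MINaT", "MAXaT",
                                             "MThm", "ANT", "TW", "TAR",
                                             "MxR", "MiR", "HrA", "HrMx",
                                             "HrMi", "THI")) {
  miss <- setdiff(variables, names(climate))
  if (length(miss)) stop("unknown climate variable(s): ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(as.data.frame(climate)[, variables, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rownames(climate)
  m
}
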