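#' Code smoking exposure into pack-years categories
#'
#' Never smokers (0 pack-years) are coded 0; ever-smokers are coded 1-3 by
#' the tertiles of pack-years computed among ever-smokers only. Tertile
#' boundaries are type-7 sample quantiles; values equal to a boundary go to
#' the lower category, so the coding is monotone in pack-years.
#'
#' @param pack_years Non-negative numeric vector.
#' @return Integer vector of codes in `0:3` (`NA` preserved).
#' @export
#' @examples
#' code_pack_years(c(0, 5, 50))
code_pack_years <- function(pack_years) {
  stopifnot(is.numeric(pack_years))
  if (any(pack_years < 0, na.rm = TRUE)) {
    stop("pack_years must be non-negative", call. = FALSE)
  }
  out <- rep(NA_integer_, length(pack_years))
  out[pack_years == 0] <- 0L
  ever <- which(!is.na(pack_years) & pack_years > 0)
  if (length(ever) > 0) {
    cuts <- quantile(pack_years[ever], c(1 / 3, 2 / 3),
                     names = FALSE, type = 7)
    out[ever] <- findInterval(pack_years[ever], cuts, left.open = TRUE) + 1L
  }
  out
}
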