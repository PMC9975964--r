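#' Seasonal calendar of representative months
#'
#' Annual PM2.5 exposure is characterized from four representative months,
#' one per local season: January (winter, Dec-Feb), May (pre-monsoon,
#' Mar-May), July (monsoon, Jun-Sep) and October (post-monsoon, Oct-Nov).
#' Each season's annual weight is the number of calendar months it
#' represents divided by 12, so the monsoon month carries the largest weight
#' (4/12) and the annual mean of a constant field is that constant.
#'
#' @param months_represented Named integer vector giving the number of
#'   calendar months each representative month stands for; must sum to 12.
#'
#' @return A tibble with columns `season`, `month`, `months_represented`
#'   and `weight` (summing to 1).
#' @examples
#' season_calendar()
#' @export
season_calendar <- function(months_represented = c(Jan = 3L, May = 3L,
                                                   Jul = 4L, Oct = 2L)) {
  months <- c("Jan", "May", "Jul", "Oct")
  if (!setequal(names(months_represented), months)) {
    abort("months_represented must be named Jan, May, Jul, Oct")
  }
  m <- as.integer(months_represented[months])
  if (any(m <= 0L) || sum(m) != 12L) {
    abort("months_represented must be positive and sum to 12",
          class = "aqhia_invalid_calendar")
  }
  tibble(
    season = c("winter", "pre-monsoon", "monsoon", "post-monsoon"),
    month = months,
    months_represented = m,
    weight = m / 12
  )
}

rep_months <- c("Jan", "May", "Jul", "Oct")

month_season <- function(month) {
  cal <- season_calendar()
  cal$season[match(month, cal$month)]
}
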