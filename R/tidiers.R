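# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an Rxy curve
#'
#' @param x an `rxy_curve`.
#' @param ... unused.
#' @return a plain tibble with `delay_frames`, `delay_s`, `rxy` (and
#'   `n_cells` for aggregates).
#' @export
tidy.rxy_curve <- function(x, ...) {
  tibble::as_tibble(unclass_keep_tbl(x))
}

#' One-row summary of an Rxy curve
#'
#' @param x an `rxy_curve`.
#' @param ... unused.
#' @return tibble with `n_cells`, `peak_rxy`, `peak_delay_frames`,
#'   `peak_delay_s`, `significant`, `threshold`.
#' @export
glance.rxy_curve <- function(x, ...) {
  ok <- !is.na(x$rxy)
  j <- which(x$rxy == max(x$rxy[ok]))[1]
  tibble::tibble(
    n_cells = attr(x, "n_cells") %||% NA_integer_,
    peak_rxy = x$rxy[j],
    peak_delay_frames = x$delay_frames[j],
    peak_delay_s = x$delay_s[j],
    significant = attr(x, "significant") %||% NA,
    threshold = attr(x, "threshold") %||% NA_real_)
}

#' Tidy a localization histogram
#'
#' @param x a `localization_histogram`.
#' @param ... unused.
#' @return tibble `segment`, `count`, `frequency`, `n_cells`.
#' @export
tidy.localization_histogram <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(unclass_keep_tbl(x)),
                n_cells = attr(x, "n_cells"))
}

#' Tidy a pole series into long format
#'
#' @param x a `pole_series`.
#' @param ... unused.
#' @return tibble `track_id`, `frame`, `pole`, `intensity_au`.
#' @export
tidy.pole_series <- function(x, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(unclass_keep_tbl(x)),
                              c("initial_leading_au", "initial_lagging_au"),
                              names_to = "pole", values_to = "intensity_au")
  long$pole <- sub("_au$", "", long$pole)
  long
}

unclass_keep_tbl <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}
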