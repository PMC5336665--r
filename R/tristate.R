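# Three-valued (Kleene) logic over logical scalars where NA means "unknown".
# Every survey/informant fact in the engine is evaluated in this logic first;
# unknowns are only resolved to met/not met by the missing-data policy at the
# criterion level (see resolve_status()).

#' Three-valued logical OR
#'
#' `TRUE` if any argument is `TRUE`; `NA` if none is `TRUE` but at least one
#' is `NA`; `FALSE` otherwise.  Scalars only.
#'
#' @param ... logical scalars (may be `NA`).
#' @return a logical scalar.
#' @keywords internal
tri_or <- function(...) {
  v <- c(...)
  if (any(v, na.rm = TRUE)) return(TRUE)
  if (anyNA(v)) return(NA)
  FALSE
}

#' Three-valued logical AND
#'
#' `FALSE` if any argument is `FALSE`; `NA` if none is `FALSE` but at least
#' one is `NA`; `TRUE` otherwise.
#'
#' @param ... logical scalars (may be `NA`).
#' @return a logical scalar.
#' @keywords internal
tri_and <- function(...) {
  v <- c(...)
  if (any(!v, na.rm = TRUE)) return(FALSE)
  if (anyNA(v)) return(NA)
  TRUE
}

#' @rdname tri_or
#' @param x logical scalar.
#' @keywords internal
tri_not <- function(x) !x

#' Convert file tristate ("yes"/"no"/NA) to three-valued logical
#' @param x character vector of `"yes"`, `"no"` or `NA`.
#' @return logical vector with `NA` for unknown.
#' @keywords internal
as_tri <- function(x) ifelse(is.na(x), NA, x == "yes")

# Any element <= cut, in three-valued logic.  Empty or all-NA input -> NA
# ("no evidence" rather than "evidence of absence").
any_le <- function(x, cut) {
  v <- unlist(x, use.names = FALSE)
  miss <- is.na(v)
  if (any(v[!miss] <= cut)) return(TRUE)
  if (any(miss) || length(v) == 0) return(NA)
  FALSE
}

# Any element inside (lo, hi] (lo_open = TRUE) or [lo, hi] (lo_open = FALSE).
any_in_range <- function(x, lo, hi, lo_open = TRUE) {
  v <- unlist(x, use.names = FALSE)
  miss <- is.na(v)
  v <- v[!miss]
  hit <- if (lo_open) (v > lo & v <= hi) else (v >= lo & v <= hi)
  if (any(hit)) return(TRUE)
  if (any(miss) || length(v) == 0) return(NA)
  FALSE
}
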