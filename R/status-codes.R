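#' Status flag states
#'
#' The tri-state semantic flag derived from raw era-specific Indigenous-status
#' codes: `"positive"` (identified as Aboriginal and/or Torres Strait
#' Islander), `"negative"` (identified as neither), `"missing"` (not stated /
#' inadequately described).
#'
#' @return Character vector of the three flag states, in display order.
#' @export
status_levels <- function() c("positive", "negative", "missing")

#' Coding eras and record sources for raw status codes
#'
#' Hospital morbidity collections switched from a legacy binary code
#' (1 = not Aboriginal, 2 = Aboriginal) to a four-category code
#' (1 = Aboriginal, 2 = Torres Strait Islander, 3 = both, 4 = neither,
#' with provision for "not stated"). `status_eras()` and `record_sources()`
#' return the admissible labels.
#'
#' @return Character vector of admissible labels.
#' @export
status_eras <- function() c("legacy_binary", "four_category")

#' @rdname status_eras
#' @export
record_sources <- function() c("hospital_public_wa", "hospital_other", "death")

#' Interpret raw Indigenous-status codes as tri-state flags
#'
#' Maps era-specific raw codes to `"positive"` / `"negative"` / `"missing"`.
#' Under the legacy binary era, 1 is negative and 2 is positive. Under the
#' four-category era, codes 1-3 (Aboriginal, Torres Strait Islander, both)
#' are positive and 4 is negative. An absent code (`NA`) is `"missing"`,
#' except in WA public hospital records, where "not stated" is keyed
#' identically to "neither" and an absent code therefore reads as negative.
#'
#' @param code Integer vector of raw codes; `NA` means absent.
#' @param era Character vector (recycled), one of [status_eras()].
#' @param source Character vector (recycled), one of [record_sources()].
#' @param tsi_as_positive Should four-category code 2 (Torres Strait Islander,
#'   not Aboriginal) count as positive? Defaults to `TRUE`, the convention
#'   used when a single combined Indigenous-status flag is analysed.
#' @return Character vector of flag states, same length as `code`.
#' @examples
#' interpret_status(2, "legacy_binary", "hospital_public_wa")   # "positive"
#' interpret_status(4, "four_category", "hospital_public_wa")   # "negative"
#' interpret_status(NA, "four_category", "death")               # "missing"
#' interpret_status(NA, "four_category", "hospital_public_wa")  # "negative"
#' @export
interpret_status <- function(code, era, source, tsi_as_positive = TRUE) {
  n <- length(code)
  era <- recycle_to(as.character(era), n, "era")
  source <- recycle_to(as.character(source), n, "source")
  check_values(era, status_eras(), "era")
  check_values(source, record_sources(), "source")
  code <- as.integer(code)

  bad_legacy <- era == "legacy_binary" & (is.na(code) | !code %in% c(1L, 2L))
  bad_four <- era == "four_category" & !(is.na(code) | code %in% 1:4)
  if (any(bad_legacy | bad_four)) {
    i <- which(bad_legacy | bad_four)[1L]
    rlang::abort(
      sprintf(
        "Invalid status code %s for era '%s' (record %d).",
        ifelse(is.na(code[i]), "<absent>", code[i]), era[i], i
      ),
      class = "ascertain_coding_error"
    )
  }

  positive_codes <- if (tsi_as_positive) 1:3 else c(1L, 3L)
  out <- rep(NA_character_, n)

  legacy <- era == "legacy_binary"
  out[legacy & code == 2L] <- "positive"
  out[legacy & code == 1L] <- "negative"

  four <- era == "four_category"
  out[four & code %in% positive_codes] <- "positive"
  out[four & !is.na(code) & !code %in% positive_codes] <- "negative"
  absent <- four & is.na(code)
  out[absent & source == "hospital_public_wa"] <- "negative"
  out[absent & source != "hospital_public_wa"] <- "missing"
  out
}

#' Recode legacy binary status codes to the four-category scheme
#'
#' The legacy value 1 (not Aboriginal) becomes 4 (neither) and the legacy
#' value 2 (Aboriginal) becomes 3 (both), mirroring the bulk recode applied
#' to hospital morbidity records when the coding scheme changed.
#'
#' @param code Integer vector with values in `{1, 2}`.
#' @return Integer vector with values in `{3, 4}`.
#' @examples
#' recode_legacy_status(c(1, 2))  # 4 3
#' @export
recode_legacy_status <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code) | !code %in% c(1L, 2L))) {
    i <- which(is.na(code) | !code %in% c(1L, 2L))[1L]
    rlang::abort(
      sprintf("Legacy status codes must be 1 or 2; got %s (element %d).",
              ifelse(is.na(code[i]), "<absent>", code[i]), i),
      class = "ascertain_coding_error"
    )
  }
  dplyr::if_else(code == 1L, 4L, 3L)
}

recycle_to <- function(x, n, what) {
  if (length(x) == n) return(x)
  if (length(x) == 1L) return(rep(x, n))
  rlang::abort(sprintf("`%s` must have length 1 or %d.", what, n))
}

check_values <- function(x, allowed, what) {
  bad <- !is.na(x) & !x %in% allowed
  if (any(bad)) {
    rlang::abort(
      sprintf("`%s` must be one of %s; got '%s'.", what,
              paste0("'", allowed, "'", collapse = ", "), x[which(bad)[1L]]),
      class = "ascertain_coding_error"
    )
  }
  if (anyNA(x)) {
    rlang::abort(sprintf("`%s` must not be missing.", what),
                 class = "ascertain_coding_error")
  }
  invisible(x)
}
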