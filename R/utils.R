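#' @importFrom rlang .data abort warn
#' @importFrom dplyr %>%
NULL

# round half away from zero to integer percent (Table-style rounding;
# base round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

# split a ";"-joined flag string into a character vector ("" -> none)
split_flags <- function(flags) {
  if (is.na(flags) || !nzchar(flags)) return(character())
  strsplit(flags, "[;,]")[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fus <- function(msg, class) {
  rlang::abort(msg, class = c(class, "fusetriage_error"))
}
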