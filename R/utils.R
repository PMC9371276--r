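# Internal helpers shared across modules.

#' @importFrom rlang %||% .data
#' @importFrom stats quantile median qnorm plogis qlogis rnorm rbinom rpois
#'   runif as.formula binomial coef glm logLik setNames
#' @importFrom utils modifyList
NULL

# Window constants (days). "18 months" and "12 months" follow-up windows are
# fixed day counts so date arithmetic is reproducible; both are configurable
# through the functions that use them.
DAYS_18_MONTHS <- 548L
DAYS_12_MONTHS <- 365L
DAYS_PER_MONTH <- 30.4375

`%d+%` <- function(date, days) date + as.difftime(days, units = "days")

as_date_safe <- function(x) {
  if (inherits(x, "Date")) return(x)
  suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
}

abort_ckdqi <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "ckdqi_error")
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
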