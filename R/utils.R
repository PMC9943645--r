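#' @keywords internal
#' @importFrom stats rbinom rpois rnorm runif sd var cor quantile qnorm
#'   setNames update median
#' @importFrom ggplot2 .data
"_PACKAGE"

# stage order is fixed throughout: seedlings, saplings, adults
STAGES <- c("R", "S", "A")

invlogit <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) & !is.na(x) & x >= 0 & abs(x - round(x)) < 1e-8
}

#' Standardization constants for model covariates
#'
#' Holds the centring/scaling constants applied to rainfall and to intra- and
#' interspecific adult densities before they enter the logit-linear survival
#' models. Constants are computed once (by the data generator or at data read
#' time) and carried with the dataset so that every downstream module uses the
#' same scale; they are never recomputed from scenario samples.
#'
#' @param rain_mean,rain_sd Mean and SD of the observed rainfall series.
#' @param intra_mean,intra_sd Centre/scale for the intraspecific adult density.
#' @param inter_mean,inter_sd Centre/scale for the summed heterospecific adult
#'   density.
#' @return An object of class `"standardization"` (a named list).
#' @export
standardization <- function(rain_mean, rain_sd,
                            intra_mean = 10, intra_sd = 5,
                            inter_mean = 10, inter_sd = 5) {
  if (rain_sd <= 0 || intra_sd <= 0 || inter_sd <= 0) {
    stopf("standardization SDs must be positive (rainfall series may be degenerate)")
  }
  structure(list(rain_mean = rain_mean, rain_sd = rain_sd,
                 intra_mean = intra_mean, intra_sd = intra_sd,
                 inter_mean = inter_mean, inter_sd = inter_sd),
            class = "standardization")
}

std_rain <- function(rain, std) (rain - std$rain_mean) / std$rain_sd
std_intra <- function(x, std) (x - std$intra_mean) / std$intra_sd
std_inter <- function(x, std) (x - std$inter_mean) / std$inter_sd
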