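#' @importFrom rlang abort warn .data :=
#' @importFrom stats quantile rnorm runif rbinom qlogis plogis qnorm glm
#'   binomial predict coef glm.control setNames dnorm integrate
#' @importFrom utils head tail
NULL

# Five-year age bands used throughout; cohorts start at 20 but younger bands
# are recognised so that under-age records can be excluded rather than error.
AGE_BANDS_ALL <- c(
  "0-4", "5-9", "10-14", "15-19",
  "20-24", "25-29", "30-34", "35-39", "40-44", "45-49", "50-54", "55-59",
  "60-64", "65-69", "70-74", "75-79", "80-84", "85-89", "90+"
)
AGE_BANDS_ADULT <- AGE_BANDS_ALL[-(1:4)]
DISEASE_LEVELS <- c("0", "1", "2", "3", "4+")

age_band_lower <- function(band) {
  as.numeric(sub("[-+].*$", "", sub("\\+$", "", as.character(band))))
}

#' Package quantile convention
#'
#' All percentiles in this package (variation ratios, winsorization cut
#' points, medians and interquartile ranges) use linear interpolation between
#' order statistics (`stats::quantile()` type 7). The convention is fixed so
#' that ratios are reproducible across runs and is stamped into report
#' metadata.
#'
#' @param x Numeric vector.
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles.
#' @export
rx_quantile <- function(x, probs) {
  quantile(x, probs = probs, type = 7, names = FALSE, na.rm = FALSE)
}

QUANTILE_CONVENTION <- "linear interpolation (type 7)"

# Derive independent substream seeds from one global seed so that, e.g.,
# adding patients does not perturb the practice draws. Kept below 2^31 - 1.
substream_seed <- function(seed, stream) {
  offsets <- c(
    practices = 101L, patients = 211L, classes = 307L,
    prescriptions = 401L, pipeline = 503L, noise = 601L
  )
  if (!stream %in% names(offsets)) {
    abort(paste0("unknown random substream: ", stream))
  }
  as.integer((as.numeric(seed) * 48271 + offsets[[stream]]) %% 2147483647)
}

with_substream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  force(code)
}

#' Round half away from zero
#'
#' Rendered percentages use half-up rounding at the displayed precision;
#' all intermediate tables carry full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt_count_pct <- function(count, denom, digits = 2) {
  pct <- ifelse(denom > 0, 100 * count / denom, 0)
  sprintf("%s (%s%%)", format(count, big.mark = " ", trim = TRUE),
          formatC(round_half_up(pct, digits), format = "f", digits = digits))
}

new_exclusion_log <- function(entity_id = character(), entity_kind = character(),
                              rule_id = character(), detail = character()) {
  tibble::tibble(
    entity_id = as.character(entity_id),
    entity_kind = as.character(entity_kind),
    rule_id = as.character(rule_id),
    detail = as.character(detail)
  )
}

log_rows <- function(ids, kind, rule, detail = "") {
  if (length(ids) == 0) return(new_exclusion_log())
  new_exclusion_log(ids, rep(kind, length(ids)), rep(rule, length(ids)),
                    rep(detail, length(ids)))
}
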