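#' Score EQ-5D-5L health states with a value set
#'
#' Maps five-digit EQ-5D-5L states (mobility, self-care, usual activities,
#' pain/discomfort, anxiety/depression; each level 1 = no problems to
#' 5 = extreme problems) to a utility index by subtracting the value-set
#' decrement of each chosen level from 1.
#'
#' @param state character vector of five-digit states (e.g. `"21121"`), or a
#'   matrix/data.frame with five columns of levels 1-5. `NA` states return
#'   `NA`.
#' @param value_set value-set table as from [default_value_set()].
#' @return numeric vector of utility indices.
#' @export
#' @examples
#' score_eq5d_index("11111", default_value_set())  # 1.0
score_eq5d_index <- function(state, value_set) {
  if (is.character(state) || is.factor(state)) {
    state <- as.character(state)
    ok <- !is.na(state)
    if (any(nchar(state[ok]) != 5L))
      stop("eq5d state must have exactly 5 digits")
    lv <- matrix(NA_integer_, length(state), 5L)
    if (any(ok)) {
      sp <- do.call(rbind, strsplit(state[ok], ""))
      lv[ok, ] <- suppressWarnings(as.integer(sp))
    }
  } else {
    lv <- as.matrix(state)
    if (ncol(lv) != 5L) stop("eq5d state matrix must have 5 columns")
    storage.mode(lv) <- "integer"
  }
  present <- !is.na(lv)
  if (any(lv[present] < 1L | lv[present] > 5L))
    stop("eq5d dimension levels must be in 1..5")
  # decrement lookup matrix [dimension, level]
  dm <- matrix(value_set$decrement[order(match(value_set$dimension,
                                               eq5d_dimensions),
                                         value_set$level)],
               nrow = 5L, byrow = TRUE)
  out <- rep(NA_real_, nrow(lv))
  complete <- rowSums(present) == 5L
  if (any(complete)) {
    idx <- lv[complete, , drop = FALSE]
    dec <- vapply(seq_len(5L), function(d) dm[d, idx[, d]],
                  numeric(sum(complete)))
    if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1L)
    out[complete] <- 1 - rowSums(dec)
  }
  out
}

#' Enumerate all 3125 EQ-5D-5L states
#' @return character vector of length 5^5 = 3125.
#' @export
enumerate_eq5d_states <- function() {
  g <- expand.grid(1:5, 1:5, 1:5, 1:5, 1:5)[, 5:1]
  apply(g, 1L, paste0, collapse = "")
}

#' Score the PHQ-9
#'
#' The PHQ-9 total is the sum of its nine items, each scored 0-3.
#'
#' @param items numeric vector of 9 items, or a matrix with 9 columns (one
#'   row per respondent). Rows with any `NA` return `NA`.
#' @return total score(s) in 0-27.
#' @export
score_phq9 <- function(items) {
  m <- if (is.null(dim(items))) matrix(items, nrow = 1L) else as.matrix(items)
  if (ncol(m) != 9L) stop("PHQ-9 requires exactly 9 items")
  pres <- !is.na(m)
  if (any(m[pres] < 0 | m[pres] > 3 | m[pres] != round(m[pres])))
    stop("PHQ-9 items must be integers in 0..3")
  tot <- rowSums(m)
  if (is.null(dim(items))) tot[[1L]] else tot
}

phq9_bands <- data.frame(
  label = c("none/minimal", "mild", "moderate", "moderately severe", "severe"),
  lower = c(0, 5, 10, 15, 20),
  upper = c(4, 9, 14, 19, 27),
  stringsAsFactors = FALSE
)

#' PHQ-9 severity band
#'
#' Standard severity bands partitioning 0-27: none/minimal (0-4), mild (5-9),
#' moderate (10-14), moderately severe (15-19), severe (20-27). Non-integer
#' totals (e.g. a sample mean) fall in the band whose closed interval
#' contains them.
#'
#' @param total PHQ-9 total score(s) in [0, 27].
#' @return character vector of band labels.
#' @export
phq9_severity <- function(total) {
  if (any(is.na(total)) || any(total < 0 | total > 27))
    stop("PHQ-9 total must be in [0, 27]")
  idx <- findInterval(total, phq9_bands$lower)
  phq9_bands$label[idx]
}

#' QALYs by area under the linearly interpolated utility curve
#'
#' Utilities at the four assessments (baseline and 1, 6, 12 months) are
#' assumed to follow a linear trend between consecutive time points; the QALY
#' contribution of each segment is its length in days times the mean of its
#' endpoint utilities, divided by the days in one year. Reference days
#' default to 30 (T0-T1), 150 (T1-T2) and 180 (T2-T3), tiling 360 follow-up
#' days.
#'
#' @param utilities numeric vector of 4 utilities, or a matrix with 4 columns
#'   (one row per participant). Any `NA` in a row yields `NA` (impute first).
#' @param reference_days segment lengths in days.
#' @param denominator days per year used to convert days to years.
#' @return QALYs accrued over the follow-up period.
#' @export
qaly_auc <- function(utilities, reference_days = c(30, 150, 180),
                     denominator = 365) {
  m <- if (is.null(dim(utilities))) matrix(utilities, nrow = 1L)
       else as.matrix(utilities)
  if (ncol(m) != length(reference_days) + 1L)
    stop("need one more utility than segments")
  seg <- sapply(seq_along(reference_days), function(s)
    reference_days[s] * (m[, s] + m[, s + 1L]) / 2)
  if (is.null(dim(seg))) seg <- matrix(seg, nrow = 1L)
  out <- rowSums(seg) / denominator
  if (is.null(dim(utilities))) out[[1L]] else out
}

#' Probability of a depression-free day given a PHQ-9 score
#'
#' A day counts as fully depression-free below a PHQ-9 of 5 (no/minimal
#' depression) and not at all at 15 or higher (moderately severe); between
#' the two anchors the probability is linearly interpolated:
#' `(15 - phq9) / 10`. The function is continuous and non-increasing.
#'
#' @param phq9 PHQ-9 score(s) in [0, 27]; may be non-integer (interpolated
#'   trajectories).
#' @return probability in [0, 1].
#' @export
dfd_probability <- function(phq9) {
  if (any(is.na(phq9)) || any(phq9 < 0 | phq9 > 27))
    stop("PHQ-9 value must be in [0, 27]")
  # first argument first so matrix inputs keep their dimensions
  pmin(pmax((15 - phq9) / 10, 0), 1)
}

# antiderivative of dfd_probability
.dfd_F <- function(x) {
  ifelse(x <= 5, x,
         ifelse(x >= 15, 10, 5 + (100 - (15 - x)^2) / 20))
}

#' Depression-free days accrued over follow-up
#'
#' PHQ-9 scores are interpolated linearly in continuous time between
#' consecutive assessments (analogous to the QALY computation) and composed
#' with [dfd_probability()]; the integral has a closed form on each segment
#' because the composition is piecewise linear. Result is reported in days.
#'
#' @inheritParams qaly_auc
#' @param scores numeric vector of 4 PHQ-9 totals, or matrix with 4 columns.
#' @return depression-free days in [0, sum(reference_days)].
#' @export
dfd_auc <- function(scores, reference_days = c(30, 150, 180)) {
  m <- if (is.null(dim(scores))) matrix(scores, nrow = 1L) else
    as.matrix(scores)
  if (ncol(m) != length(reference_days) + 1L)
    stop("need one more score than segments")
  pres <- !is.na(m)
  if (any(m[pres] < 0 | m[pres] > 27)) stop("PHQ-9 value must be in [0, 27]")
  total <- numeric(nrow(m))
  for (s in seq_along(reference_days)) {
    a <- m[, s]; b <- m[, s + 1L]; d <- reference_days[s]
    flat <- !is.na(a) & !is.na(b) & a == b
    seg <- rep(NA_real_, nrow(m))
    seg[flat] <- d * dfd_probability(a[flat])
    sl <- !is.na(a) & !is.na(b) & a != b
    if (any(sl)) {
      lo <- pmin(a[sl], b[sl]); hi <- pmax(a[sl], b[sl])
      seg[sl] <- d * (.dfd_F(hi) - .dfd_F(lo)) / (hi - lo)
    }
    total <- total + seg
  }
  if (is.null(dim(scores))) total[[1L]] else total
}
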