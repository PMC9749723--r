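#' Landmark grid
#'
#' The set of landmark ages at which prediction is made, and the fixed
#' prediction horizon. The default grid is the integer ages 40 through 85
#' (46 landmark ages) with a 10-year horizon.
#'
#' @param ages integer landmark ages (years).
#' @param horizon prediction window w (years), > 0.
#' @return an object of class `lmv_grid`.
#' @export
landmark_grid <- function(ages = 40:85, horizon = 10) {
  stopifnot(length(ages) >= 1, horizon > 0)
  structure(list(ages = as.numeric(ages), horizon = horizon),
            class = "lmv_grid")
}

# restrict a series to the pre-landmark window [30, s): measurements taken
# at exactly the landmark age are not available for prediction at it
restrict_series <- function(series, s) {
  series[series$age >= 30 & series$age < s, , drop = FALSE]
}

#' Pre-landmark summaries of one measurement series
#'
#' Summaries of a single subject's series of one risk factor using only
#' measurements in the half-open window `[30, s)`: the last observed
#' value, the cumulative crude mean, and the within-person sample SD
#' (n - 1 denominator), the latter defined only for subjects with at
#' least two prior measurements.
#'
#' @param series data frame with columns `age` and `value`.
#' @param s landmark age (years).
#' @return a single numeric value; `NA` when undefined (no prior
#'   measurement; fewer than two for the SD).
#' @export
summarize_last <- function(series, s) {
  r <- restrict_series(series, s)
  if (nrow(r) == 0) return(NA_real_)
  r$value[which.max(r$age)]
}

#' @rdname summarize_last
#' @export
summarize_mean <- function(series, s) {
  r <- restrict_series(series, s)
  if (nrow(r) == 0) return(NA_real_)
  mean(r$value)
}

#' @rdname summarize_last
#' @export
summarize_sd <- function(series, s) {
  r <- restrict_series(series, s)
  if (nrow(r) < 2) return(NA_real_)
  stats::sd(r$value)
}

#' Build the stacked landmark dataset
#'
#' For every landmark age s in the grid, selects the subjects who are
#' under follow-up and event-free at s, have type 2 diabetes diagnosed
#' on/before s and — in complete-case mode — at least one pre-landmark
#' measurement of every continuous factor plus an observed smoking
#' status. Each eligible (subject, s) pair becomes one record carrying
#' the Stage-1 summaries of all measurements in `[30, s)`, the binary
#' covariates defined as ever-before-s, diabetes duration, and the
#' outcome truncated at the horizon `s + w` (an event at exactly `s + w`
#' counts as in-horizon).
#'
#' Columns `<factor>_current` / `<factor>_slope` are initialised to `NA`
#' and filled by [add_mixed_summaries()].
#'
#' @param cohort an `lmv_cohort`.
#' @param grid a [landmark_grid()].
#' @param mode `"complete_case"` (the primary analysis population) or
#'   `"any_measurement"` (at least one pre-landmark observation of any
#'   factor or of smoking status; unobserved smoking is coded 0).
#' @return data frame of landmark records, one row per eligible
#'   (subject, landmark age).
#' @export
build_landmark_dataset <- function(cohort, grid,
                                   mode = c("complete_case", "any_measurement")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "lmv_grid"))
  if (length(grid$ages) == 0) stop("empty landmark grid", call. = FALSE)
  sub <- cohort$subjects
  meas <- cohort$measurements
  smoke <- cohort$smoking
  w <- grid$horizon
  S <- grid$ages
  fkey <- tolower(RISK_FACTORS)

  meas_split <- if (nrow(meas))
    split(meas[c("age", "value")], list(meas$subject_id, meas$factor), drop = TRUE)
  else list()
  smoke_split <- if (nrow(smoke))
    split(smoke[c("age", "current_smoker")], smoke$subject_id, drop = TRUE)
  else list()

  out <- vector("list", nrow(sub))
  for (i in seq_len(nrow(sub))) {
    p <- sub[i, ]
    s_ok <- S >= p$entry_age & S < p$exit_age & S >= p$diabetes_dx_age
    if (!any(s_ok)) next
    ss <- S[s_ok]

    nmat <- matrix(0L, length(ss), length(RISK_FACTORS),
                   dimnames = list(NULL, fkey))
    last <- mean_ <- sdv <- matrix(NA_real_, length(ss), length(RISK_FACTORS),
                                   dimnames = list(NULL, fkey))
    for (ki in seq_along(RISK_FACTORS)) {
      k <- RISK_FACTORS[ki]
      ser <- meas_split[[paste(p$subject_id, k, sep = ".")]]
      if (is.null(ser) || nrow(ser) == 0) next
      keep <- ser$age >= 30
      a <- ser$age[keep]; v <- ser$value[keep]
      if (!length(a)) next
      o <- order(a); a <- a[o]; v <- v[o]
      cs <- cumsum(v); cs2 <- cumsum(v^2)
      nk <- findInterval(ss, a, left.open = TRUE)  # #{ages < s}
      pos <- nk > 0
      nmat[, ki] <- nk
      last[pos, ki] <- v[nk[pos]]
      mu <- cs[nk[pos]] / nk[pos]
      mean_[pos, ki] <- mu
      two <- nk >= 2
      if (any(two)) {
        ssq <- cs2[nk[two]] - nk[two] * (cs[nk[two]] / nk[two])^2
        sdv[two, ki] <- sqrt(pmax(ssq, 0) / (nk[two] - 1))
      }
    }

    sm <- smoke_split[[as.character(p$subject_id)]]
    smoking_last <- rep(NA_integer_, length(ss))
    if (!is.null(sm) && nrow(sm)) {
      keep <- sm$age >= 30
      sa <- sm$age[keep]; sv <- sm$current_smoker[keep]
      o <- order(sa); sa <- sa[o]; sv <- sv[o]
      ns <- findInterval(ss, sa, left.open = TRUE)
      smoking_last[ns > 0] <- sv[ns[ns > 0]]
    }

    if (mode == "complete_case") {
      keep <- rowSums(nmat >= 1) == length(RISK_FACTORS) & !is.na(smoking_last)
    } else {
      keep <- rowSums(nmat >= 1) > 0 | !is.na(smoking_last)
      smoking_last[is.na(smoking_last)] <- 0L
    }
    if (!any(keep)) next
    ss <- ss[keep]
    nmat <- nmat[keep, , drop = FALSE]
    last <- last[keep, , drop = FALSE]
    mean_ <- mean_[keep, , drop = FALSE]
    sdv <- sdv[keep, , drop = FALSE]
    smoking_last <- smoking_last[keep]

    rec <- data.frame(
      subject_id = p$subject_id, practice_id = p$practice_id, sex = p$sex,
      ethnicity = p$ethnicity, landmark_age = ss)
    for (ki in seq_along(fkey)) {
      rec[[paste0(fkey[ki], "_last")]] <- last[, ki]
      rec[[paste0(fkey[ki], "_mean")]] <- mean_[, ki]
      rec[[paste0(fkey[ki], "_sd")]] <- sdv[, ki]
      rec[[paste0(fkey[ki], "_n")]] <- nmat[, ki]
      rec[[paste0(fkey[ki], "_current")]] <- NA_real_
      rec[[paste0(fkey[ki], "_slope")]] <- NA_real_
    }
    rec$smoking_last <- smoking_last
    rec$bp_med_ever <- as.integer(!is.na(p$bp_med_first_age) &
                                    p$bp_med_first_age < ss)
    rec$af_ever <- as.integer(!is.na(p$af_dx_age) & p$af_dx_age < ss)
    rec$diabetes_duration <- ss - p$diabetes_dx_age
    rec$follow_time <- pmin(p$exit_age, ss + w) - ss
    rec$event_in_horizon <- as.integer(p$event_indicator == 1 &
                                         p$exit_age <= ss + w)
    out[[i]] <- rec
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    warning("no eligible (subject, landmark) pairs", call. = FALSE)
    return(empty_landmark_frame())
  }
  rownames(out) <- NULL
  out
}

empty_landmark_frame <- function() {
  fkey <- tolower(RISK_FACTORS)
  cols <- c("subject_id", "practice_id", "sex", "ethnicity", "landmark_age",
            as.vector(t(outer(fkey, c("_last", "_mean", "_sd", "_n",
                                      "_current", "_slope"), paste0))),
            "smoking_last", "bp_med_ever", "af_ever", "diabetes_duration",
            "follow_time", "event_in_horizon")
  df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  df$sex <- character(0); df$ethnicity <- character(0)
  df
}

#' Restrict landmark records to subjects with many repeated measures
#'
#' Keeps the records whose every continuous factor has at least `k_min`
#' pre-landmark measurements — the subgroups in which SD-augmented models
#' are examined.
#'
#' @param records landmark dataset from [build_landmark_dataset()].
#' @param k_min minimum number of measurements per factor (>= 2).
#' @return the subset of `records`.
#' @export
subgroup_by_measurement_count <- function(records, k_min) {
  if (k_min < 2) stop("k_min must be >= 2", call. = FALSE)
  ncols <- paste0(tolower(RISK_FACTORS), "_n")
  keep <- rowSums(as.matrix(records[ncols]) >= k_min) == length(ncols)
  records[keep, , drop = FALSE]
}
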