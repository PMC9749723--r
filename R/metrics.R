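#' Harrell's C-index for censored horizon outcomes
#'
#' Proportion of concordant pairs among comparable pairs. A pair is
#' comparable iff the strictly shorter follow-up time ends in an event;
#' it is concordant when the earlier-event member has the higher
#' predicted risk, and prediction ties count 1/2. Pairs with exactly
#' equal times are not comparable under this convention.
#'
#' Computation is delegated to [survival::concordance()] (with risk
#' direction reversed) whenever no event time ties another record's time,
#' in which case the two conventions coincide; with such ties an exact
#' pair count under the stated convention is used.
#'
#' @param predictions predicted risks (higher = riskier).
#' @param follow_time follow-up times.
#' @param event_in_horizon 0/1 event indicators.
#' @return concordance in `[0, 1]`.
#' @export
harrell_c <- function(predictions, follow_time, event_in_horizon) {
  n <- length(predictions)
  stopifnot(length(follow_time) == n, length(event_in_horizon) == n)
  if (n < 2) stop("at least two records are required", call. = FALSE)
  ev_times <- follow_time[event_in_horizon == 1]
  if (length(ev_times) == 0)
    stop("no comparable pairs: no events", call. = FALSE)

  # survival::concordance agrees with the strict convention except on
  # pairs where an event time equals a censoring time (it treats the
  # censored member as surviving longer; the strict convention drops the
  # pair). Event-event time ties are incomparable under both.
  cens_times <- follow_time[event_in_horizon != 1]
  event_censor_tie <- any(ev_times %in% cens_times)
  if (!event_censor_tie) {
    cf <- survival::concordance(
      survival::Surv(follow_time, event_in_horizon) ~ predictions,
      reverse = TRUE)
    npairs <- sum(cf$count[c("concordant", "discordant", "tied.x")])
    if (npairs == 0) stop("no comparable pairs", call. = FALSE)
    return(unname(cf$concordance))
  }
  # exact count under the strict shorter-time-is-an-event convention
  conc <- 0; total <- 0
  for (i in which(event_in_horizon == 1)) {
    longer <- follow_time > follow_time[i]
    total <- total + sum(longer)
    conc <- conc + sum(predictions[i] > predictions[longer]) +
      0.5 * sum(predictions[i] == predictions[longer])
  }
  if (total == 0) stop("no comparable pairs", call. = FALSE)
  conc / total
}

# Kaplan-Meier of the censoring distribution, returned as an evaluator
# giving G(t) (right-continuous) and G(t-) (left limit)
censoring_km <- function(follow_time, event_in_horizon) {
  cf <- survival::survfit(survival::Surv(follow_time, 1 - event_in_horizon) ~ 1)
  tt <- cf$time; ss <- cf$surv
  list(
    at = function(t) {
      idx <- findInterval(t, tt)
      ifelse(idx == 0, 1, ss[pmax(idx, 1)])
    },
    at_minus = function(t) {
      idx <- findInterval(t, tt, left.open = TRUE)  # steps strictly before t
      ifelse(idx == 0, 1, ss[pmax(idx, 1)])
    })
}

#' Brier score for w-year risk with IPCW censoring weights
#'
#' Mean squared difference between the predicted w-year risk and the
#' w-year outcome status. Under censoring, the Graf
#' inverse-probability-of-censoring weighting is used with the
#' Kaplan-Meier censoring survivor function G: subjects with an event at
#' T <= w get weight 1/G(T-), subjects under follow-up at w (or censored
#' exactly at w) get weight 1/G(w-), and subjects censored strictly
#' before w contribute zero; the sum is divided by the total number of
#' records. With no censoring all weights are 1 and the score reduces to
#' the plain mean squared error.
#'
#' @param predictions predicted w-year risks in `[0, 1]`.
#' @param follow_time follow-up times.
#' @param event_in_horizon 0/1 event indicators.
#' @param w horizon (years).
#' @param ipcw set `FALSE` for the unweighted variant (mean squared error
#'   over records with a determinate w-year status).
#' @return non-negative score.
#' @export
brier_score <- function(predictions, follow_time, event_in_horizon, w = 10,
                        ipcw = TRUE) {
  n <- length(predictions)
  stopifnot(length(follow_time) == n, length(event_in_horizon) == n)
  is_event <- event_in_horizon == 1 & follow_time <= w
  is_survivor <- follow_time >= w & !is_event
  if (!ipcw) {
    keep <- is_event | is_survivor
    return(mean((predictions[keep] - as.numeric(is_event[keep]))^2))
  }
  G <- censoring_km(follow_time, event_in_horizon)
  wts <- numeric(n)
  ge <- G$at_minus(follow_time[is_event])
  gw <- G$at_minus(w)
  if (any(ge <= 0) || (any(is_survivor) && gw <= 0))
    stop("censoring Kaplan-Meier reaches zero before the horizon; ",
         "truncate the horizon", call. = FALSE)
  wts[is_event] <- 1 / ge
  wts[is_survivor] <- 1 / gw
  sum(wts * (predictions - as.numeric(is_event))^2) / n
}

#' Kaplan-Meier event probability by a horizon
#'
#' Estimates `P(event by w)` as one minus the Kaplan-Meier survivor
#' function at `w`, accounting for censoring before the horizon.
#'
#' @param follow_time follow-up time on the landmark time scale.
#' @param event_in_horizon 0/1 event indicator.
#' @param w horizon.
#' @return scalar probability.
#' @export
km_event_prob <- function(follow_time, event_in_horizon, w) {
  if (length(follow_time) == 0) return(NA_real_)
  sf <- survival::survfit(survival::Surv(follow_time, event_in_horizon) ~ 1)
  idx <- findInterval(w, sf$time)
  s <- if (idx == 0) 1 else sf$surv[idx]
  1 - s
}

#' Continuous net reclassification improvement at a horizon
#'
#' Kaplan-Meier-adjusted continuous NRI of new vs old predictions:
#' among events, the net proportion assigned a higher risk by the new
#' model; among non-events, the net proportion assigned a lower risk;
#' the NRI is their sum. Event status at the horizon is estimated by
#' Kaplan-Meier within the up-classified, down-classified and overall
#' groups, which reduces to the direct 2x2 count formulation when there
#' is no censoring.
#'
#' @param pred_new,pred_old paired predictions on the same records.
#' @param follow_time follow-up times.
#' @param event_in_horizon 0/1 event indicators.
#' @param w horizon (years).
#' @return list with `nri`, `nri_events`, `nri_nonevents`.
#' @export
continuous_nri <- function(pred_new, pred_old, follow_time, event_in_horizon,
                           w = 10) {
  n <- length(pred_new)
  if (length(pred_old) != n || length(follow_time) != n ||
      length(event_in_horizon) != n)
    stop("pred_new, pred_old and outcomes must be paired on identical records",
         call. = FALSE)
  up <- pred_new > pred_old
  down <- pred_new < pred_old
  p_up <- mean(up); p_down <- mean(down)
  pe_all <- km_event_prob(follow_time, event_in_horizon, w)
  pe_up <- if (any(up)) km_event_prob(follow_time[up], event_in_horizon[up], w) else 0
  pe_down <- if (any(down)) km_event_prob(follow_time[down], event_in_horizon[down], w) else 0
  if (is.na(pe_all) || pe_all <= 0 || pe_all >= 1)
    stop("overall event probability at the horizon is degenerate", call. = FALSE)
  nri_events <- (p_up * pe_up - p_down * pe_down) / pe_all
  nri_nonevents <- (p_down * (1 - pe_down) - p_up * (1 - pe_up)) / (1 - pe_all)
  list(nri = nri_events + nri_nonevents,
       nri_events = nri_events, nri_nonevents = nri_nonevents)
}

#' Calibration slope of predicted risks, by landmark-age bin
#'
#' Per bin, the coefficient of the prognostic index
#' `log(-log(1 - predicted risk))` in a Cox model on the bin's records;
#' 1 indicates neither over- nor under-dispersion of the predictions.
#' Single-year landmark-age bins are merged upward until each holds at
#' least `min_events` events; a degenerate bin (no events, or a constant
#' index) yields `NA` with the reason recorded.
#'
#' @param predictions predicted w-year risks.
#' @param follow_time follow-up times.
#' @param event_in_horizon 0/1 event indicators.
#' @param landmark_age landmark ages; `NULL` for a single overall bin.
#' @param min_events minimum events per age bin before closing it.
#' @return data frame with `age_lo`, `age_hi`, `n`, `events`, `slope`,
#'   `reason` (`NA` when the slope is defined).
#' @export
calibration_slope <- function(predictions, follow_time, event_in_horizon,
                              landmark_age = NULL, min_events = 20) {
  n <- length(predictions)
  if (is.null(landmark_age)) landmark_age <- rep(0, n)
  stopifnot(length(follow_time) == n, length(event_in_horizon) == n,
            length(landmark_age) == n)
  pr <- pmin(pmax(predictions, 1e-12), 1 - 1e-12)
  pi_idx <- log(-log(1 - pr))

  ages <- sort(unique(landmark_age))
  bins <- list(); cur <- c()
  cur_events <- 0
  for (a in ages) {
    cur <- c(cur, a)
    cur_events <- cur_events + sum(event_in_horizon[landmark_age == a])
    if (cur_events >= min_events) {
      bins[[length(bins) + 1]] <- cur
      cur <- c(); cur_events <- 0
    }
  }
  if (length(cur)) {
    if (length(bins)) bins[[length(bins)]] <- c(bins[[length(bins)]], cur)
    else bins[[1]] <- cur
  }

  rows <- lapply(bins, function(bn) {
    sel <- landmark_age %in% bn
    ev <- sum(event_in_horizon[sel])
    slope <- NA_real_; reason <- NA_character_
    if (ev == 0) {
      reason <- "no events"
    } else if (stats::var(pi_idx[sel]) < 1e-12) {
      reason <- "constant prognostic index"
    } else {
      fit <- tryCatch(
        survival::coxph(survival::Surv(follow_time[sel],
                                       event_in_horizon[sel]) ~ pi_idx[sel],
                        ties = "efron"),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit) || anyNA(stats::coef(fit))) reason <- "fit failed"
      else slope <- unname(stats::coef(fit))
    }
    data.frame(age_lo = min(bn), age_hi = max(bn), n = sum(sel), events = ev,
               slope = slope, reason = reason)
  })
  do.call(rbind, rows)
}

#' Cluster-bootstrap percentile confidence interval
#'
#' Resamples clusters (subjects) with replacement — all of a subject's
#' landmark records move together — and returns the percentile interval
#' of the metric over replicates. Errors in more than 5% of replicates
#' abort.
#'
#' @param metric_fn function taking a data frame of records and returning
#'   a scalar.
#' @param records data frame with a `subject_id` column.
#' @param n_boot number of replicates (>= 200 recommended).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list with `lo`, `hi` and the replicate values.
#' @export
bootstrap_ci <- function(metric_fn, records, n_boot = 200, seed = 1L,
                         conf = 0.95) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  idx_by_subj <- split(seq_len(nrow(records)), records$subject_id)
  subj <- names(idx_by_subj)
  reps <- numeric(n_boot)
  fails <- 0
  for (b in seq_len(n_boot)) {
    take <- sample(subj, length(subj), replace = TRUE)
    ix <- unlist(idx_by_subj[take], use.names = FALSE)
    reps[b] <- tryCatch(metric_fn(records[ix, , drop = FALSE]),
                        error = function(e) { fails <<- fails + 1; NA_real_ })
  }
  if (fails > 0.05 * n_boot)
    stop(sprintf("metric failed in %d of %d bootstrap replicates",
                 fails, n_boot), call. = FALSE)
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(lo = qs[1], hi = qs[2], replicates = reps)
}
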