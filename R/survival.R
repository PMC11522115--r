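#' Survival analysis with blanking and AAD censoring rules
#'
#' One-year atrial-fibrillation-free, antiarrhythmic-drug(AAD)-free survival:
#' patients enter the curve after a 90-day blanking period; only AAD-free
#' days accrue survival time; a recurrence while on an AAD cannot count as an
#' AAD-free event and instead censors the patient at the last AAD-free
#' follow-up date; patients whose entire post-blanking follow-up was on an
#' AAD are excluded.
#'
#' @name survival-rules
NULL

# merge intervals (two-column matrix start/end) into disjoint sorted form
.merge_intervals <- function(starts, ends) {
  ends[is.na(ends)] <- Inf
  if (length(starts) == 0) return(cbind(start = numeric(0), end = numeric(0)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out <- list()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) {
      me <- max(me, ends[i])
    } else {
      out[[length(out) + 1]] <- c(ms, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  out[[length(out) + 1]] <- c(ms, me)
  mat <- do.call(rbind, out)
  colnames(mat) <- c("start", "end")
  mat
}

# AAD-free time in the window (from, to], given merged intervals
.aad_free_time <- function(from, to, intervals) {
  if (to <= from) return(0)
  total <- to - from
  if (nrow(intervals) == 0) return(total)
  overlap <- sum(pmax(0, pmin(intervals[, "end"], to) -
                        pmax(intervals[, "start"], from)))
  total - overlap
}

# last time point at or before `day` not covered by intervals, or -Inf
.last_free_day <- function(day, intervals) {
  if (nrow(intervals) == 0) return(day)
  for (i in rev(seq_len(nrow(intervals)))) {
    if (day > intervals[i, "end"]) return(day)
    if (day >= intervals[i, "start"]) day <- intervals[i, "start"]
  }
  day
}

# convert *_date columns to day offsets from ablation_date when present
.followup_days <- function(followup) {
  fu <- as_tibble(followup)
  date_mode <- "ablation_date" %in% names(fu)
  day_of <- function(col_date, col_day) {
    if (col_day %in% names(fu)) return(as.numeric(fu[[col_day]]))
    if (date_mode && col_date %in% names(fu)) {
      return(as.numeric(as.Date(fu[[col_date]]) - as.Date(fu$ablation_date)))
    }
    rep(NA_real_, nrow(fu))
  }
  tibble(patient_id = fu$patient_id,
         recurrence_day = day_of("recurrence_date", "recurrence_day"),
         last_followup_day = day_of("last_followup_date", "last_followup_day"),
         last_aad_free_day = day_of("last_aad_free_date", "last_aad_free_day"),
         recurrence_on_aad = if ("recurrence_on_aad" %in% names(fu)) {
           as.logical(fu$recurrence_on_aad)
         } else NA,
         erc = if ("erc" %in% names(fu)) as.logical(fu$erc) else NA)
}

#' Build survival entries from follow-up records
#'
#' Applies the study rules to per-patient follow-up: recurrences inside the
#' blanking period are ignored; a recurrence off AAD after blanking is an
#' event; a recurrence on AAD censors at the last AAD-free follow-up date;
#' patients with no AAD-free follow-up after blanking are excluded; and all
#' survivors are administratively censored at `horizon_days` on the survival
#' clock. The survival clock counts only AAD-free days after the end of
#' blanking -- days spent on an AAD pause the clock (set
#' `aad_gap = "reset"` to restart it after each AAD interval instead).
#'
#' @param followup Data frame with one row per patient. Time columns may be
#'   day offsets from ablation (`recurrence_day`, `last_followup_day`,
#'   optional `last_aad_free_day`) or dates (`ablation_date`,
#'   `recurrence_date`, `last_followup_date`, `last_aad_free_date`).
#'   Optional: `recurrence_on_aad` (derived from the AAD intervals when
#'   absent) and `erc` (logical; defines the comparison groups).
#' @param aad_intervals Optional data frame of AAD usage spells:
#'   `patient_id`, `start_day`/`start_date`, `end_day`/`end_date` (missing
#'   end = ongoing). Overlapping spells are merged.
#' @param blanking_days Blanking period in days (default 90).
#' @param horizon_days Administrative censoring horizon on the survival
#'   clock, in days (default 365).
#' @param aad_gap `"pause"` (default) or `"reset"`; see Details.
#' @param quiet Suppress the entered/excluded message.
#' @return Tibble of class `erc_survival_entries` with columns
#'   `patient_id`, `time` (days), `event`, `group` (factor `non-ERC`/`ERC`,
#'   or `all`). Excluded patients are absent; their reasons are in the
#'   attribute `"exclusions"` (see [survival_exclusions()]). Entry count
#'   plus exclusion count always equals the input patient count.
#' @export
build_survival_entries <- function(followup, aad_intervals = NULL,
                                   blanking_days = 90, horizon_days = 365,
                                   aad_gap = c("pause", "reset"),
                                   quiet = FALSE) {
  aad_gap <- match.arg(aad_gap)
  fu <- .followup_days(followup)
  if (anyDuplicated(fu$patient_id)) abort("patient_id must be unique in followup")
  aad <- if (is.null(aad_intervals)) {
    tibble(patient_id = character(0), start_day = numeric(0), end_day = numeric(0))
  } else {
    ai <- as_tibble(aad_intervals)
    if (!"start_day" %in% names(ai) && "start_date" %in% names(ai)) {
      abl <- setNames(as.Date(followup$ablation_date), followup$patient_id)
      ai$start_day <- as.numeric(as.Date(ai$start_date) - abl[ai$patient_id])
      ai$end_day <- as.numeric(as.Date(ai$end_date) - abl[ai$patient_id])
    }
    ai
  }
  entries <- list()
  exclusions <- list()
  for (i in seq_len(nrow(fu))) {
    p <- fu[i, ]
    iv <- aad |> filter(.data$patient_id == p$patient_id)
    ints <- .merge_intervals(iv$start_day, iv$end_day)
    exclude <- function(reason) {
      exclusions[[length(exclusions) + 1]] <<-
        tibble(patient_id = p$patient_id, reason = reason)
    }
    clock <- function(endpoint) {
      if (aad_gap == "pause") {
        .aad_free_time(blanking_days, endpoint, ints)
      } else {
        prior_ends <- ints[ints[, "end"] <= endpoint, "end"]
        start <- max(c(blanking_days, prior_ends))
        .aad_free_time(start, endpoint, ints)
      }
    }
    if (is.na(p$last_followup_day)) {
      exclude("missing_followup"); next
    }
    bad_dates <- p$last_followup_day < 0 ||
      (!is.na(p$recurrence_day) &&
         (p$recurrence_day < 0 || p$recurrence_day > p$last_followup_day))
    if (bad_dates) {
      exclude("inconsistent_dates"); next
    }
    rec <- p$recurrence_day
    if (!is.na(rec) && rec <= blanking_days) rec <- NA_real_  # blanking: ignored
    if (!is.na(rec)) {
      on_aad <- if (!is.na(p$recurrence_on_aad)) {
        p$recurrence_on_aad
      } else {
        nrow(ints) > 0 && any(rec > ints[, "start"] & rec <= ints[, "end"])
      }
      if (!on_aad) {
        time <- clock(rec); event <- TRUE
      } else {
        last_free <- if (!is.na(p$last_aad_free_day)) {
          p$last_aad_free_day
        } else {
          .last_free_day(rec, ints)
        }
        if (last_free <= blanking_days) {
          exclude("recurrence_on_aad_without_aad_free_followup"); next
        }
        time <- clock(last_free); event <- FALSE
      }
    } else {
      time <- clock(p$last_followup_day)
      event <- FALSE
      if (time <= 0) {
        exclude("no_aad_free_followup"); next
      }
    }
    if (time > horizon_days) {  # administrative censoring at the horizon
      time <- horizon_days; event <- FALSE
    }
    entries[[length(entries) + 1]] <-
      tibble(patient_id = p$patient_id, time = time, event = event,
             erc = p$erc)
  }
  out <- if (length(entries)) list_rbind(entries) else {
    tibble(patient_id = character(0), time = numeric(0),
           event = logical(0), erc = logical(0))
  }
  out$group <- if (all(is.na(out$erc))) {
    factor(rep("all", nrow(out)))
  } else {
    factor(ifelse(out$erc, "ERC", "non-ERC"), levels = c("non-ERC", "ERC"))
  }
  out$erc <- NULL
  excl <- if (length(exclusions)) list_rbind(exclusions) else {
    tibble(patient_id = character(0), reason = character(0))
  }
  if (!quiet) {
    inform(paste0("build_survival_entries: ", nrow(out), " patients entered, ",
                  nrow(excl), " excluded"))
  }
  attr(out, "exclusions") <- excl
  class(out) <- c("erc_survival_entries", class(out))
  out
}

#' Exclusion log of a survival-entry table
#'
#' @param entries Result of [build_survival_entries()].
#' @return Tibble with `patient_id` and `reason` for every excluded patient.
#' @export
survival_exclusions <- function(entries) {
  attr(entries, "exclusions") %||%
    tibble(patient_id = character(0), reason = character(0))
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator per group, computed with [survival::survfit()];
#' censorings at an event time are processed after the events at that time,
#' the standard convention. A time-0 row with survival 1 is prepended per
#' group for plotting.
#'
#' @param entries Tibble with `time`, `event`, and optionally `group`.
#' @return Tibble of class `erc_km`: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `estimate`, `std_error`, `conf_low`, `conf_high`. The
#'   underlying `survfit` object is kept in attribute `"survfit"`.
#' @export
km_estimate <- function(entries) {
  entries <- as_tibble(entries)
  if (nrow(entries) < 1) abort("need at least one survival entry")
  if (!"group" %in% names(entries)) entries$group <- factor("all")
  entries$group <- droplevels(as.factor(entries$group))
  single <- nlevels(entries$group) == 1
  sf <- if (single) {
    survfit(Surv(time, event) ~ 1, data = entries)
  } else {
    survfit(Surv(time, event) ~ group, data = entries)
  }
  groups <- if (single) {
    rep(levels(entries$group), length(sf$time))
  } else {
    rep(sub("^group=", "", names(sf$strata)), sf$strata)
  }
  tab <- tibble(group = factor(groups, levels = levels(entries$group)),
                time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                n_censor = sf$n.censor, estimate = sf$surv,
                std_error = sf$std.err * sf$surv,  # survfit std.err is on log scale
                conf_low = sf$lower, conf_high = sf$upper)
  zero <- tab |>
    distinct(.data$group) |>
    mutate(time = 0, n_risk = NA_integer_, n_event = 0L, n_censor = 0L,
           estimate = 1, std_error = 0, conf_low = 1, conf_high = 1)
  out <- bind_rows(zero, tab) |> arrange(.data$group, .data$time)
  attr(out, "survfit") <- sf
  class(out) <- c("erc_km", class(out))
  out
}

#' Survival probability at given times
#'
#' Step-function lookup of the Kaplan-Meier estimate: the probability of
#' remaining AF-free at each requested time.
#'
#' @param km An [km_estimate()] result (or an entries tibble, which is
#'   estimated first).
#' @param times Times (days on the survival clock).
#' @param group Group to look up; defaults to the only group.
#' @return Numeric survival probabilities.
#' @export
km_survival_at <- function(km, times, group = NULL) {
  if (!inherits(km, "erc_km")) km <- km_estimate(km)
  groups <- levels(km$group)
  if (is.null(group)) {
    if (length(groups) > 1) abort("specify `group` for a multi-group estimate")
    group <- groups[1]
  }
  sub <- km[km$group == group, ]
  sf <- stats::stepfun(sub$time[-1], sub$estimate, right = FALSE)
  sf(times)
}

#' Two-group log-rank test
#'
#' Standard log-rank test (1 degree of freedom for two groups), computed
#' with [survival::survdiff()]; the p-value comes from the chi-square
#' distribution without continuity correction.
#'
#' @param entries Tibble with `time`, `event`, `group` (two or more levels,
#'   each with at least one entry).
#' @return One-row tibble: `chi_square`, `df`, `p_value`, plus per-group
#'   observed and expected event counts in attribute `"obs_exp"`.
#' @export
log_rank <- function(entries) {
  entries <- as_tibble(entries)
  if (!"group" %in% names(entries)) abort("log_rank needs a group column")
  entries$group <- droplevels(as.factor(entries$group))
  k <- nlevels(entries$group)
  if (k < 2) abort("log_rank needs at least two non-empty groups")
  sd <- survdiff(Surv(time, event) ~ group, data = entries)
  df <- k - 1
  out <- tibble(chi_square = unname(sd$chisq), df = df,
                p_value = pchisq(sd$chisq, df = df, lower.tail = FALSE))
  attr(out, "obs_exp") <- tibble(group = sub("^group=", "", names(sd$n)),
                                 n = as.integer(sd$n),
                                 observed = sd$obs, expected = sd$exp)
  out
}

#' @rdname km_estimate
#' @param object An `erc_km` object.
#' @param ... Unused.
#' @export
autoplot.erc_km <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$estimate,
                               colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "AAD-free days since end of blanking",
                  y = "AF-free survival", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname km_estimate
#' @param x An `erc_km` object.
#' @export
glance.erc_km <- function(x, ...) {
  x |>
    group_by(.data$group) |>
    summarise(n_events = sum(.data$n_event),
              n_censored = sum(.data$n_censor),
              final_estimate = .data$estimate[which.max(.data$time)],
              .groups = "drop")
}
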