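## Deterministic clinical scores and ventilation-derived outcome variables.

#' Oxygenation index
#'
#' OI = (mean airway pressure x FiO2 x 100) / PaO2. Higher values indicate
#' worse gas exchange.
#'
#' @param map_cmH2O Mean airway pressure (cmH2O).
#' @param fio2 Inspired oxygen fraction in (0, 1].
#' @param pao2 Arterial oxygen tension (mmHg), > 0.
#' @return Unitless oxygenation index.
#' @examples
#' oxygenation_index(10, 0.5, 50)  # 10
#' @export
oxygenation_index <- function(map_cmH2O, fio2, pao2) {
  if (any(pao2 <= 0)) stop_domain("pao2 must be positive")
  if (any(fio2 <= 0 | fio2 > 1)) stop_domain("fio2 must lie in (0, 1]")
  map_cmH2O * fio2 * 100 / pao2
}

#' PaO2/FiO2 ratio
#'
#' @param pao2 Arterial oxygen tension (mmHg).
#' @param fio2 Inspired oxygen fraction, > 0.
#' @return P/F ratio in mmHg.
#' @export
pf_ratio <- function(pao2, fio2) {
  if (any(fio2 <= 0)) stop_domain("fio2 must be positive")
  pao2 / fio2
}

#' Vasopressor score
#'
#' Weighted sum of vasoactive infusion rates: dopamine x 1 + dobutamine x 1
#' + epinephrine x 100 + norepinephrine x 100 + phenylephrine x 100 +
#' milrinone x 10 + vasopressin x 10,000. All rates in ug/kg/min except
#' vasopressin (U/kg/min). Absent drugs count as 0.
#'
#' @param dopamine,dobutamine,epinephrine,norepinephrine,phenylephrine,milrinone
#'   Infusion rates in ug/kg/min (non-negative).
#' @param vasopressin Infusion rate in U/kg/min (non-negative).
#' @return Unitless score.
#' @examples
#' vasopressor_score(epinephrine = 0.1)  # 10
#' @export
vasopressor_score <- function(dopamine = 0, dobutamine = 0, epinephrine = 0,
                              norepinephrine = 0, phenylephrine = 0,
                              milrinone = 0, vasopressin = 0) {
  doses <- cbind(dopamine, dobutamine, epinephrine, norepinephrine,
                 phenylephrine, milrinone, vasopressin)
  if (any(doses < 0)) stop_domain("vasoactive doses must be non-negative")
  w <- c(1, 1, 100, 100, 100, 10, 10000)
  as.numeric(doses %*% w)
}

# merge ventilation intervals whose extubation gap is <= gap_threshold days
# (liberation not achieved); returns a matrix of merged [start, end) spans
merge_vent_intervals <- function(start, end, gap_threshold = 1) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (any(end <= start)) stop_domain("ventilation intervals need end > start")
  if (length(start) > 1 && any(start[-1] < end[-length(end)])) {
    stop_domain("overlapping ventilation intervals")
  }
  ms <- start[1]; me <- end[1]
  out <- NULL
  for (i in seq_along(start)[-1]) {
    if (start[i] - me <= gap_threshold) {
      me <- end[i]
    } else {
      out <- rbind(out, c(ms, me))
      ms <- start[i]; me <- end[i]
    }
  }
  rbind(out, c(ms, me))
}

#' Total ventilator days for one subject
#'
#' Liberation from invasive ventilation for more than `gap_threshold` days
#' (24 h) defines the end of a ventilation course: an extubation gap of at
#' most 24 h merges the adjacent intervals (the gap itself counts as
#' ventilation, since liberation was not achieved), while reintubation more
#' than 24 h after extubation starts a new course whose days are added to
#' the total.
#'
#' @param start,end Numeric vectors of interval starts/ends in days from
#'   ARDS onset; half-open `[start, end)`.
#' @param gap_threshold Liberation threshold in days (default 1 = 24 h);
#'   a gap of exactly 24 h does not count as liberation.
#' @return Total ventilator days (non-negative real).
#' @examples
#' ventilator_days(c(0, 5.5), c(5, 6))  # 6: gap of 0.5 d merges
#' ventilator_days(c(0, 8), c(5, 10))   # 7: sustained liberation at day 5
#' @export
ventilator_days <- function(start, end, gap_threshold = 1) {
  spans <- merge_vent_intervals(start, end, gap_threshold)
  sum(spans[, 2] - spans[, 1])
}

#' Ventilator-free days at 28 days
#'
#' VFD = 28 minus total ventilator days in survivors; PICU nonsurvivors and
#' subjects ventilated 28 days or more are assigned VFD = 0. Partial
#' ventilator days are counted as whole days (rounded up) before
#' subtraction, so reported VFDs are integers.
#'
#' @param vent_days Total ventilator days (see [ventilator_days()]).
#' @param picu_survivor Logical: survived the PICU stay.
#' @param round_up Count partial days as whole days (default TRUE).
#' @return Integer VFD in 0..28.
#' @export
vfd28 <- function(vent_days, picu_survivor, round_up = TRUE) {
  if (any(vent_days < 0)) stop_domain("vent_days must be non-negative")
  vd <- if (round_up) ceiling(vent_days) else vent_days
  out <- pmax(0, 28 - vd)
  out[!picu_survivor] <- 0
  as.integer(out)
}

#' Immunocompromised designation
#'
#' A subject is designated immunocompromised if an immunocompromising
#' diagnosis (oncologic, immunologic, rheumatologic, or transplant) is
#' present together with active immunosuppressive therapy, or if a
#' congenital immunodeficiency is present.
#'
#' @param oncologic,immunologic,rheumatologic,transplant Diagnosis flags.
#' @param active_therapy Active immunosuppressive therapy flag.
#' @param congenital Congenital immunodeficiency flag.
#' @return Logical.
#' @export
classify_immunocompromised <- function(oncologic = FALSE, immunologic = FALSE,
                                       rheumatologic = FALSE, transplant = FALSE,
                                       active_therapy = FALSE,
                                       congenital = FALSE) {
  ((oncologic | immunologic | rheumatologic | transplant) & active_therapy) |
    congenital
}

#' Per-subject outcome summary from an event-history table
#'
#' Reduces the interval-level events table to one row per subject with
#' total ventilator days (24-h merge rule), VFD at 28 days, and the
#' competing-risk representation used by the extubation analysis: `time`
#' in (0, 28] and `event` coded 0 = censored ventilated at day 28,
#' 1 = sustained extubation alive, 2 = death. The event time is the first
#' sustained liberation (> 24 h extubated); death before that time is the
#' competing event; ties go to death.
#'
#' @param events Validated events table (see [validate_events()]).
#' @param horizon Administrative censoring day (default 28).
#' @return Data frame: subject_id, vent_days, picu_survivor, vfd, time, event.
#' @export
events_summary <- function(events, horizon = EVENT_HORIZON) {
  events <- validate_events(events)
  ids <- unique(events$subject_id)
  out <- lapply(ids, function(sid) {
    rows <- events[events$subject_id == sid, , drop = FALSE]
    spans <- merge_vent_intervals(rows$vent_start, rows$vent_end)
    vd <- sum(spans[, 2] - spans[, 1])
    surv <- rows$picu_survivor[1]
    dd <- rows$death_day[1]
    lib <- spans[1, 2]  # first sustained liberation
    if (!is.na(dd) && dd <= lib) {
      time <- dd; event <- 2L
    } else if (lib < horizon) {
      time <- lib; event <- 1L
    } else if (!is.na(dd)) {
      # still ventilated at liberation >= horizon, but death recorded
      time <- min(dd, horizon)
      event <- if (dd <= horizon) 2L else 0L
    } else {
      time <- horizon; event <- 0L
    }
    data.frame(subject_id = sid, vent_days = vd, picu_survivor = surv,
               vfd = vfd28(vd, surv), time = time, event = event,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
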