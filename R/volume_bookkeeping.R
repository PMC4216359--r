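#' Carbon-monoxide dilution record
#'
#' Bundles the measurements of one CO-rebreathing labelling session used to
#' estimate circulating red-cell volume: the administered CO dose, the pre- and
#' post-labelling carboxyhemoglobin fractions, total blood hemoglobin and the
#' simultaneous hematocrit.
#'
#' @param co_dose CO volume administered, ml STPD. Must be > 0.
#' @param cohb_pre,cohb_post carboxyhemoglobin fractions (0-1) before and after
#'   labelling; `cohb_post` must exceed `cohb_pre`.
#' @param cthb blood hemoglobin concentration, g/l. Must be > 0.
#' @param hct hematocrit as a fraction in (0, 1).
#'
#' @return An object of class `co_dilution_record`.
#' @seealso [estimate_vrbc_co()]
#' @export
#' @examples
#' co_dilution_record(17.6, 0.012, 0.062, cthb = 86, hct = 0.277)
co_dilution_record <- function(co_dose, cohb_pre, cohb_post, cthb, hct) {
  stop_unless(is_number(co_dose) && co_dose > 0, "co_dose must be a positive number")
  stop_unless(is_number(cthb) && cthb > 0, "cthb must be a positive number (g/l)")
  stop_unless(is_number(hct) && hct > 0 && hct < 1,
              "hct must be a fraction strictly between 0 and 1")
  stop_unless(is_number(cohb_pre) && is_number(cohb_post) &&
                cohb_pre >= 0 && cohb_post <= 1,
              "COHb fractions must lie in [0, 1]")
  if (cohb_post <= cohb_pre) {
    stop("no measurable label uptake: cohb_post must exceed cohb_pre", call. = FALSE)
  }
  structure(
    list(co_dose = co_dose, cohb_pre = cohb_pre, cohb_post = cohb_post,
         cthb = cthb, hct = hct),
    class = "co_dilution_record"
  )
}

#' Red-cell volume from CO dilution
#'
#' Estimates circulating red-cell volume from a carbon-monoxide labelling
#' session. The CO dose divided by the rise in carboxyhemoglobin fraction gives
#' circulating hemoglobin mass through the Huefner binding capacity (1.39 ml CO
#' bound per g Hb); hemoglobin mass over blood hemoglobin concentration gives
#' blood volume, and the hematocrit fraction of that is red-cell volume. No
#' whole-body/venous hematocrit (f-cell) correction is applied.
#'
#' @param rec a [co_dilution_record()].
#' @param hufner CO binding capacity of hemoglobin, ml CO (STPD) per g Hb.
#' @return Red-cell volume in ml (strictly positive).
#' @export
#' @examples
#' rec <- co_dilution_record(17.6, 0.01, 0.06, cthb = 86, hct = 0.277)
#' estimate_vrbc_co(rec) # ~816 ml
estimate_vrbc_co <- function(rec, hufner = 1.39) {
  stopifnot(inherits(rec, "co_dilution_record"))
  stop_unless(is_number(hufner) && hufner > 0, "hufner must be positive")
  thb_g <- rec$co_dose / (hufner * (rec$cohb_post - rec$cohb_pre))
  blood_ml <- thb_g / rec$cthb * 1000
  blood_ml * rec$hct
}

#' Plasma volume from red-cell volume and hematocrit
#'
#' `PV = V_RBC (1 - Hct) / Hct`. Vectorised over both arguments.
#'
#' @param vrbc red-cell volume, ml (> 0).
#' @param hct hematocrit fraction in (0, 1).
#' @return Plasma volume in the units of `vrbc`.
#' @export
#' @examples
#' plasma_volume(816, 0.277)
plasma_volume <- function(vrbc, hct) {
  stop_unless(is.numeric(vrbc) && all(is.finite(vrbc)) && all(vrbc > 0),
              "vrbc must be positive and finite")
  stop_unless(is.numeric(hct) && all(is.finite(hct)) && all(hct > 0 & hct < 1),
              "hct must be a fraction strictly between 0 and 1")
  vrbc * (1 - hct) / hct
}

#' Propagate red-cell volume through recorded blood losses
#'
#' Starting from the tracer-dilution baseline, red-cell volume at each grid time
#' is the baseline minus the red cells contained in all blood lost up to and
#' including that time (`volume * hct_at_event` per event). Red-cell volume is
#' otherwise conserved: crystalloid infusion and urine do not change it.
#'
#' @param vrbc0 baseline red-cell volume, ml (> 0).
#' @param events `data.frame` with columns `time` (min), `volume` (ml of whole
#'   blood lost, >= 0) and `hct` (fraction at the event). May have zero rows.
#' @param grid numeric vector of grid times (min), ascending.
#' @return `data.frame` with columns `time` and `vrbc` (ml).
#' @export
update_vrbc <- function(vrbc0, events = NULL, grid) {
  stop_unless(is_number(vrbc0) && vrbc0 > 0, "vrbc0 must be a positive number")
  stop_unless(is.numeric(grid) && length(grid) >= 1 && !is.unsorted(grid),
              "grid must be an ascending numeric vector")
  if (is.null(events) || nrow(events) == 0) {
    return(data.frame(time = grid, vrbc = rep(vrbc0, length(grid))))
  }
  stop_unless(all(c("time", "volume", "hct") %in% names(events)),
              "events needs columns time, volume, hct")
  stop_unless(all(events$volume >= 0), "event volumes must be non-negative")
  stop_unless(all(events$hct > 0 & events$hct < 1),
              "event hct must be a fraction strictly between 0 and 1")
  events <- events[order(events$time), , drop = FALSE]
  rbc_loss <- events$volume * events$hct
  vrbc <- vapply(grid, function(t) vrbc0 - sum(rbc_loss[events$time <= t]),
                 numeric(1))
  if (any(vrbc <= 0)) {
    stop("bookkeeping exhausted red-cell volume: cumulative red-cell loss ",
         "reaches baseline V_RBC", call. = FALSE)
  }
  data.frame(time = grid, vrbc = vrbc)
}

#' Fill missing hematocrit values on a grid by linear interpolation
#'
#' Interpolates interior `NA`s between the neighbouring measurements;
#' extrapolation beyond the first or last measured value is refused.
#'
#' @param time grid times (min), ascending.
#' @param hct hematocrit fractions, possibly with interior `NA`s.
#' @return `hct` with interior `NA`s filled.
#' @export
fill_hct <- function(time, hct) {
  stop_unless(length(time) == length(hct), "time and hct lengths differ")
  if (!anyNA(hct)) return(hct)
  obs <- !is.na(hct)
  stop_unless(sum(obs) >= 2, "need at least two hematocrit measurements")
  if (is.na(hct[1L]) || is.na(hct[length(hct)])) {
    stop("hematocrit missing at the edge of the grid; extrapolation is not ",
         "performed", call. = FALSE)
  }
  stats::approx(time[obs], hct[obs], xout = time, method = "linear")$y
}

#' Red-cell and plasma volume series on the measurement grid
#'
#' Combines the tracer-dilution baseline, the blood-loss ledger and repeated
#' hematocrit measurements into per-time red-cell volume, plasma volume and,
#' when a body weight is given, weight-normalised plasma volume.
#'
#' @param vrbc0 baseline red-cell volume, ml (from [estimate_vrbc_co()]).
#' @param time grid times, min.
#' @param hct hematocrit fraction at each grid time (interior `NA`s are
#'   interpolated via [fill_hct()]).
#' @param events optional blood-loss ledger, see [update_vrbc()].
#' @param weight optional body weight, kg, for `pv_per_kg`.
#' @return `data.frame` with columns `time`, `hct`, `vrbc`, `pv` and (when
#'   `weight` is given) `pv_per_kg`.
#' @export
volume_series <- function(vrbc0, time, hct, events = NULL, weight = NULL) {
  hct <- fill_hct(time, hct)
  vr <- update_vrbc(vrbc0, events, time)
  out <- data.frame(time = time, hct = hct, vrbc = vr$vrbc,
                    pv = plasma_volume(vr$vrbc, hct))
  if (!is.null(weight)) {
    stop_unless(is_number(weight) && weight > 0, "weight must be positive")
    out$pv_per_kg <- out$pv / weight
  }
  out
}
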