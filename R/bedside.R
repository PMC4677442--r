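# Bedside calculators: NIHSS total score and weight-based tPA dosing.

#' The 15-item NIHSS instrument
#'
#' Item names and maximum scores of the standard 15-item National Institutes
#' of Health Stroke Scale; the total ranges 0-42. Encoded as data so the
#' instrument can be inspected or re-skinned without touching code.
#'
#' @return A tibble with columns `item`, `label`, `max_score`.
#' @export
nihss_items <- function() {
  tibble(
    item = c("loc", "loc_questions", "loc_commands", "best_gaze",
             "visual_fields", "facial_palsy", "motor_arm_left",
             "motor_arm_right", "motor_leg_left", "motor_leg_right",
             "limb_ataxia", "sensory", "best_language", "dysarthria",
             "extinction_inattention"),
    label = c("Level of consciousness", "LOC questions", "LOC commands",
              "Best gaze", "Visual fields", "Facial palsy",
              "Motor arm (left)", "Motor arm (right)", "Motor leg (left)",
              "Motor leg (right)", "Limb ataxia", "Sensory",
              "Best language", "Dysarthria", "Extinction and inattention"),
    max_score = c(3L, 2L, 2L, 2L, 3L, 3L, 4L, 4L, 4L, 4L, 2L, 2L, 3L, 2L, 2L)
  )
}

#' NIHSS total score
#'
#' Sums a complete 15-item NIHSS assessment after validating each item
#' against its allowed range. The order of items does not matter.
#'
#' @param form Named list or named numeric vector keyed by the `item` names
#'   of [nihss_items()], each an integer within `[0, max_score]`.
#' @return Integer total in `[0, 42]`.
#' @export
#' @examples
#' form <- setNames(as.list(rep(0, 15)), nihss_items()$item)
#' nihss_total(form) # 0
nihss_total <- function(form) {
  spec <- nihss_items()
  form <- as.list(form)
  missing <- setdiff(spec$item, names(form))
  if (length(missing)) {
    abort(paste("NIHSS form missing items:", paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(form), spec$item)
  if (length(unknown)) {
    abort(paste("Unknown NIHSS items:", paste(unknown, collapse = ", ")))
  }
  vals <- vapply(spec$item, function(it) {
    v <- form[[it]]
    maxv <- spec$max_score[spec$item == it]
    if (length(v) != 1 || is.na(v) || v != as.integer(v) || v < 0 || v > maxv) {
      abort(sprintf("NIHSS item '%s' out of range [0, %d]: %s",
                    it, maxv, paste(v, collapse = ",")))
    }
    as.integer(v)
  }, integer(1))
  sum(vals)
}

#' Weight-based tPA dose plan
#'
#' Standard licensed regimen for intravenous alteplase in acute ischemic
#' stroke: `rate_mg_per_kg` (default 0.9 mg/kg) up to a ceiling of
#' `max_mg` (default 90 mg), with `bolus_fraction` (default 10%) given as
#' an initial bolus and the remainder infused. Doses are rounded to 0.1 mg.
#'
#' @param weight_kg Positive body weight in kilograms.
#' @param rate_mg_per_kg,max_mg,bolus_fraction Regimen parameters;
#'   override only for protocol variants.
#' @return A one-row tibble: `weight_kg`, `total_dose_mg`, `bolus_mg`,
#'   `infusion_mg`, `capped` (TRUE when the ceiling binds).
#' @export
#' @examples
#' tpa_dose(80)  # total 72.0, bolus 7.2, infusion 64.8
#' tpa_dose(120) # capped at 90 mg
tpa_dose <- function(weight_kg, rate_mg_per_kg = 0.9, max_mg = 90,
                     bolus_fraction = 0.1) {
  if (!is.numeric(weight_kg) || length(weight_kg) != 1 || is.na(weight_kg) ||
      weight_kg <= 0) {
    abort("weight_kg must be a single positive number")
  }
  raw <- rate_mg_per_kg * weight_kg
  capped <- raw > max_mg
  total <- round_half_up(min(raw, max_mg), 1)
  bolus <- round_half_up(bolus_fraction * total, 1)
  tibble(weight_kg = weight_kg, total_dose_mg = total, bolus_mg = bolus,
         infusion_mg = round(total - bolus, 1), capped = capped)
}
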