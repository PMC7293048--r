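#' Ordinal efficacy scale
#'
#' The nine combined tier labels in decreasing predicted-silencing order.
#' The scale is the product of the position scale (D2 strongest ... D5
#' weakest: accumulation and efficacy fall with distance from the miR173
#' target site) and the 3'-complementarity scale (0-1 mismatches `full`,
#' 2-3 `diminished`, 4-5 `abolished`), with `abolished` absorbing the
#' position factor. `(full, D2)` is named `maximal`.
#'
#' @return Character vector of labels, strongest first.
#' @export
tier_levels <- function() {
  c("maximal", "full:D3", "full:D4", "full:D5",
    "diminished:D2", "diminished:D3", "diminished:D4", "diminished:D5",
    "abolished")
}

#' Predicted efficacy tier of a (position, 3'-mismatch) design setting
#'
#' The two tuning modules are treated as independent ordinal factors:
#' precursor position 3'Dk\[+\] (rank k-1; D2 ranks highest) and the number
#' of consecutive guide-3'-end mismatches m (0-1 full complementarity
#' class, 2-3 diminished, 4-5 abolished). `abolished` absorbs position;
#' otherwise the combined label is the lexical pair of class and position.
#' Deterministic and vectorized; each row carries a plain-language
#' rationale.
#'
#' @param position Integer vector, precursor positions in 2..5.
#' @param mismatches Integer vector, consecutive 3'-end mismatches in 0..5.
#' @return A tibble of class `tasitune_efficacy_tier`: `position`,
#'   `mismatches`, `position_rank`, `complementarity_class`,
#'   `combined_label` (ordered factor over [tier_levels()]), `rationale`.
#' @examples
#' efficacy_tier(2, 0)  # maximal
#' @export
efficacy_tier <- function(position, mismatches) {
  position <- as.integer(position)
  mismatches <- as.integer(mismatches)
  if (length(position) != length(mismatches)) {
    n <- max(length(position), length(mismatches))
    position <- rep_len(position, n)
    mismatches <- rep_len(mismatches, n)
  }
  if (any(is.na(position)) || any(position < 2L | position > 5L)) {
    abort("position must be in 2..5 (3'D2[+]..3'D5[+])", class = "tasitune_input_error")
  }
  if (any(is.na(mismatches)) || any(mismatches < 0L | mismatches > 5L)) {
    abort("mismatches must be in 0..5", class = "tasitune_input_error")
  }
  class_ <- ifelse(mismatches <= 1L, "full",
                   ifelse(mismatches <= 3L, "diminished", "abolished"))
  label <- ifelse(class_ == "abolished", "abolished",
                  ifelse(class_ == "full" & position == 2L, "maximal",
                         paste0(class_, ":D", position)))
  out <- tibble(
    position = position, mismatches = mismatches,
    position_rank = position - 1L,
    complementarity_class = class_,
    combined_label = factor(label, levels = tier_levels(), ordered = TRUE),
    rationale = sprintf(
      "position 3'D%d[+] (rank %d of 4; accumulation falls with distance from the miR173 target site); %d consecutive 3'-end mismatch(es): %s complementarity (0-1 tolerated, 2-3 diminish, 4-5 abolish silencing)",
      position, position - 1L, mismatches, class_)
  )
  class(out) <- c("tasitune_efficacy_tier", class(out))
  out
}

#' The exhaustive 24-cell design grid
#'
#' All combinations of position (2..5) and consecutive 3'-end mismatches
#' (0..5) with their predicted tiers.
#'
#' @return A `tasitune_efficacy_tier` tibble with 24 rows.
#' @export
efficacy_grid <- function() {
  g <- expand.grid(mismatches = 0:5, position = 2:5)
  efficacy_tier(g$position, g$mismatches)
}

#' Design settings that realize a requested efficacy tier
#'
#' The inverse of [efficacy_tier()]: all (position, mismatches) settings
#' whose combined label matches the request, ordered by fewer mismatches,
#' then more proximal position. Inverse-consistent: every setting appears
#' in the plan for its own tier.
#'
#' @param requested A label from [tier_levels()].
#' @return A `tasitune_efficacy_tier` tibble of matching settings.
#' @examples
#' plan_settings("maximal")  # (D2, 0) and (D2, 1)
#' @export
plan_settings <- function(requested) {
  if (length(requested) != 1L || !requested %in% tier_levels()) {
    abort(sprintf("unknown tier label '%s'; see tier_levels()", requested),
          class = "tasitune_input_error")
  }
  g <- efficacy_grid()
  g <- dplyr::filter(g, as.character(.data$combined_label) == requested)
  dplyr::arrange(g, .data$mismatches, .data$position)
}
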