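#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pairing profile into its per-position table
#' @param x A [pairing_profile()] result.
#' @param ... Unused.
#' @return A tibble: `position`, `guide_base`, `site_base`, `label`.
#' @method tidy tasitune_pairing_profile
#' @export
tidy.tasitune_pairing_profile <- function(x, ...) x$pairs

#' One-row summary of a pairing profile
#' @inheritParams tidy.tasitune_pairing_profile
#' @return A one-row tibble of counts and the 3'-terminal mismatch run.
#' @method glance tasitune_pairing_profile
#' @export
glance.tasitune_pairing_profile <- function(x, ...) {
  tibble(guide = x$guide_name, site = x$site_id,
         n_mismatch = x$n_mismatch, n_wobble = x$n_wobble,
         three_prime_run = x$three_prime_run)
}

#' Tidy an off-target report into its hit table
#' @param x A [scan_transcriptome()] report.
#' @param ... Unused.
#' @return The hit tibble, ascending score.
#' @method tidy tasitune_offtarget_report
#' @export
tidy.tasitune_offtarget_report <- function(x, ...) x$hits

#' One-row summary of an off-target report
#' @inheritParams tidy.tasitune_offtarget_report
#' @return A one-row tibble: guide, hit count, minimum unintended score,
#'   cutoff and pass flag.
#' @method glance tasitune_offtarget_report
#' @export
glance.tasitune_offtarget_report <- function(x, ...) {
  tibble(guide = x$guide$name, n_hits = nrow(x$hits),
         min_unintended_score = x$min_unintended_score,
         cutoff = x$cutoff, pass = x$pass)
}

#' Tidy a variant series into its variant table
#' @param x A [make_mismatch_series()] result.
#' @param ... Unused.
#' @return The variant tibble (`k`, `name`, `guide`, `three_prime_run`,
#'   `offtarget_pass`).
#' @method tidy tasitune_variant_series
#' @export
tidy.tasitune_variant_series <- function(x, ...) x$variants

#' Tidy a precursor construct into its slot-assignment table
#' @param x A [assemble_precursor()] result.
#' @param ... Unused.
#' @return The assignment tibble (`position`, `slot`, `name`, `sequence`,
#'   `role`).
#' @method tidy tasitune_precursor_construct
#' @export
tidy.tasitune_precursor_construct <- function(x, ...) x$assignments

#' One-row summary of a precursor construct
#' @inheritParams tidy.tasitune_precursor_construct
#' @return A one-row tibble with construct and core sizes.
#' @method glance tasitune_precursor_construct
#' @export
glance.tasitune_precursor_construct <- function(x, ...) {
  tibble(length = nchar(x$assembled_sequence), core_length = nchar(x$core),
         k_max = x$k_max, n_guides = sum(x$assignments$role == "guide"),
         cleavage_offset = x$cleavage_offset)
}

#' Tidy an oligo pair
#' @param x A [design_oligos()] result.
#' @param ... Unused.
#' @return A two-row tibble: `oligo`, `overhang`, `sequence`, `length`.
#' @method tidy tasitune_oligo_pair
#' @export
tidy.tasitune_oligo_pair <- function(x, ...) {
  tibble(oligo = c("top", "bottom"),
         overhang = c(substr(x$top, 1, 4), substr(x$bottom, 1, 4)),
         sequence = c(x$top, x$bottom),
         length = c(nchar(x$top), nchar(x$bottom)))
}

#' Plot the efficacy-tier design grid
#'
#' Tile map of precursor position against 3'-end mismatch count, filled by
#' the ordinal combined tier.
#'
#' @param object A [efficacy_grid()] / [efficacy_tier()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tasitune_efficacy_tier
#' @export
autoplot.tasitune_efficacy_tier <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$mismatches),
    y = factor(sprintf("3'D%d[+]", .data$position),
               levels = sprintf("3'D%d[+]", 5:2)),
    fill = .data$combined_label)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_viridis_d(direction = -1, drop = FALSE,
                                  name = "predicted tier") +
    ggplot2::labs(x = "consecutive 3'-end mismatches",
                  y = "precursor position",
                  title = "Two-module efficacy tuning grid") +
    ggplot2::theme_minimal()
}

#' Plot an off-target report
#'
#' Reported site scores per transcript, with the specificity cutoff.
#'
#' @param object A [scan_transcriptome()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tasitune_offtarget_report
#' @export
autoplot.tasitune_offtarget_report <- function(object, ...) {
  ggplot2::ggplot(object$hits, ggplot2::aes(
    x = .data$score, y = .data$transcript_id, color = .data$intended)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(x = "site penalty score (0 = perfect)", y = NULL,
                  color = "intended target",
                  title = sprintf("Off-target scan: %s (%s)", object$guide$name,
                                  if (object$pass) "pass" else "fail")) +
    ggplot2::theme_minimal()
}

#' Plot a 3'-end mismatch variant series
#'
#' 3'-terminal mismatch run per variant, colored by the sensitivity tier it
#' implies.
#'
#' @param object A [make_mismatch_series()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tasitune_variant_series
#' @export
autoplot.tasitune_variant_series <- function(object, ...) {
  v <- object$variants
  v$tier <- vapply(v$three_prime_run,
                   function(r) classify_sensitivity(r)$label, character(1))
  ggplot2::ggplot(v, ggplot2::aes(x = factor(.data$k), y = .data$three_prime_run,
                                  fill = .data$tier)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "variant (k consecutive 3'-end substitutions)",
                  y = "3'-terminal mismatch run",
                  title = sprintf("Variant series of %s", object$parent$name)) +
    ggplot2::theme_minimal()
}
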