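#' Default configuration
#'
#' All tunable constants of the package in one nested list. Values can be
#' overridden from a JSON file (same nesting) and/or by `...` arguments of
#' the form `section.key = value`.
#'
#' Sections:
#' \describe{
#'   \item{pairing}{`guide_length` (21 nt, the DCL4 product size),
#'     `seed_start`/`seed_end` (guide positions 2-13, the seed region where
#'     mismatches are most deleterious).}
#'   \item{offtarget}{TargetFinder-style penalties: `mismatch` (1),
#'     `wobble` (0.5, a G:U pair is penalized but is not a mismatch),
#'     `bulge` (1, reserved; gapless scanning only), `seed_multiplier`
#'     (2, penalties doubled inside the seed), `cutoff` (4, a guide fails
#'     specificity if any unintended transcript scores <= cutoff), and
#'     `bulges` (FALSE).}
#'   \item{design}{Guide heuristics approximating the published designer
#'     rules: `require_5p_U`, `require_pos19_C`, `gc_min`/`gc_max`
#'     (0.30-0.60), `max_homopolymer` (4), `forbid_bsai` (no BsaI site in
#'     the guide or its complement, required by the cloning chemistry).}
#'   \item{enzyme}{The type IIS enzyme record: `recognition` ("GGTCTC"),
#'     `spacer` (1) and `overhang` (4): BsaI cuts 1 nt downstream of its
#'     site leaving 4-nt 5' overhangs.}
#'   \item{series}{`k_max` (5): up to five consecutive 3'-end mismatches.}
#' }
#'
#' @param file Optional path to a JSON file with overrides.
#' @param ... Named overrides, e.g. `offtarget.cutoff = 2`.
#' @return A nested named list.
#' @export
tasitune_config <- function(file = NULL, ...) {
  cfg <- list(
    pairing = list(guide_length = 21L, seed_start = 2L, seed_end = 13L),
    offtarget = list(mismatch = 1, wobble = 0.5, bulge = 1,
                     seed_multiplier = 2, cutoff = 4, bulges = FALSE),
    design = list(require_5p_U = TRUE, require_pos19_C = TRUE,
                  gc_min = 0.30, gc_max = 0.60, max_homopolymer = 4L,
                  forbid_bsai = TRUE),
    enzyme = list(recognition = "GGTCTC", spacer = 1L, overhang = 4L),
    series = list(k_max = 5L)
  )
  if (!is.null(file)) {
    cfg <- modify_config(cfg, jsonlite::read_json(file, simplifyVector = TRUE))
  }
  dots <- list(...)
  if (length(dots)) {
    for (nm in names(dots)) {
      path <- strsplit(nm, ".", fixed = TRUE)[[1]]
      if (length(path) != 2L || is.null(cfg[[path[1]]])) {
        abort(sprintf("unknown config key '%s'", nm), class = "tasitune_input_error")
      }
      cfg[[path[1]]][[path[2]]] <- dots[[nm]]
    }
  }
  cfg
}

modify_config <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_config(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}
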