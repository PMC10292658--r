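#' Default measure definitions for synthetic cohorts
#'
#' Each measure has a within-group factor (`factor2`; `NULL` for a single
#' overall level), per-level baseline means, a residual SD and an
#' animal-level random-intercept SD (giving repeated measures their
#' within-animal correlation). Values chosen to resemble the corresponding
#' assays: a percent-CR learning curve rising over 12 sessions, two rotarod
#' days, per-lobule Purkinje linear densities, and per-cell spine density.
#'
#' @return named list of measure definitions.
#' @export
default_cohort_measures <- function() {
  list(
    percent_cr = list(factor2 = "session", levels = 1:12,
                      mean = seq(10, 65, length.out = 12),
                      sd = 12, animal_sd = 8),
    latency_s = list(factor2 = "day", levels = 1:2,
                     mean = c(180, 220), sd = 40, animal_sd = 25),
    linear_density = list(factor2 = "lobule",
                          levels = c("I/II", "III", "IV/V", "VI", "VII",
                                     "VIII", "IX", "X"),
                          mean = rep(3.2, 8), sd = 0.4, animal_sd = 0.25),
    spine_density = list(factor2 = NULL, levels = "overall",
                         mean = 1.5, sd = 0.2, animal_sd = 0),
    soma_area = list(factor2 = NULL, levels = "overall",
                     mean = 350, sd = 50, animal_sd = 0)
  )
}

#' Generate a tidy synthetic cohort table
#'
#' Simulates per-animal measurements for a strain x sex design. Each
#' animal gets a Gaussian random intercept per measure; residual noise is
#' added per factor level; `effects` are additive shifts applied to the
#' BTBR rows of the named measure (zero effects give null cohorts for
#' type-I calibration).
#'
#' @param design data frame with `strain`, `sex`, `n` (animals per cell,
#'   >= 2).
#' @param effects named list, e.g. `list(percent_cr = -20)`; names must
#'   match measures.
#' @param seed integer seed.
#' @param measures measure definitions, defaulting to
#'   [default_cohort_measures()].
#' @param shifted_strain strain level receiving the effects (default
#'   `"BTBR"`).
#' @return tidy data frame `animal_id`, `strain`, `sex`, `measure`,
#'   `factor2`, `value`.
#' @export
generate_cohort <- function(design, effects = list(), seed = 1L,
                            measures = default_cohort_measures(),
                            shifted_strain = "BTBR") {
  stopifnot(all(c("strain", "sex", "n") %in% names(design)))
  if (any(design$n < 2)) stop_invalid("need n >= 2 animals per design cell")
  unknown <- setdiff(names(effects), names(measures))
  if (length(unknown) > 0) {
    stop_invalid("unknown measure name(s) in `effects`: ",
                 paste(unknown, collapse = ", "))
  }
  withr::with_seed(as.integer(seed), {
    rows <- list()
    aid <- 0L
    for (ci in seq_len(nrow(design))) {
      for (k in seq_len(design$n[ci])) {
        aid <- aid + 1L
        id <- sprintf("%s_%s_%02d", design$strain[ci], design$sex[ci], k)
        for (mn in names(measures)) {
          ms <- measures[[mn]]
          intercept <- if (ms$animal_sd > 0) rnorm(1, 0, ms$animal_sd) else 0
          shift <- if (!is.null(effects[[mn]]) &&
                       design$strain[ci] == shifted_strain)
            effects[[mn]] else 0
          vals <- ms$mean + intercept + shift +
            rnorm(length(ms$levels), 0, ms$sd)
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = id, strain = design$strain[ci], sex = design$sex[ci],
            measure = mn, factor2 = as.character(ms$levels), value = vals)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
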