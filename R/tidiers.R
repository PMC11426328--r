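# broom-style tidiers for the fitted result objects.

#' Tidy a Kaplan-Meier curve
#'
#' @param x An `eein_km` object from [km_curve()].
#' @param ... Unused.
#' @return A tibble with one row per distinct time (`time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`).
#' @method tidy eein_km
#' @export
tidy.eein_km <- function(x, ...) {
  class(x) <- setdiff(class(x), "eein_km")
  x
}

#' @rdname tidy.eein_km
#' @method glance eein_km
#' @export
glance.eein_km <- function(x, ...) {
  med <- x$time[x$survival <= 0.5][1]
  tibble(
    n = attr(x, "n"),
    n_events = sum(x$n_event),
    n_censored = sum(x$n_censor),
    median_survival = if (is.na(med)) NA_real_ else med
  )
}

#' Tidy a logrank test result
#'
#' @param x An `eein_logrank` object from [logrank_test()].
#' @param ... Unused.
#' @return A one-row tibble with `chisq`, `df`, `p`, group sizes and the
#'   observed-minus-expected events of the first group.
#' @method tidy eein_logrank
#' @export
tidy.eein_logrank <- function(x, ...) {
  class(x) <- setdiff(class(x), "eein_logrank")
  x
}

#' @rdname tidy.eein_logrank
#' @method glance eein_logrank
#' @export
glance.eein_logrank <- function(x, ...) {
  tibble(statistic = x$chisq, df = x$df, p.value = x$p)
}

#' Tidy a biomarker test result
#'
#' @param x An `eein_biomarker` object from [biomarker_test()].
#' @param ... Unused.
#' @return A one-row tibble without the permutation p-value list
#'   columns.
#' @method tidy eein_biomarker
#' @export
tidy.eein_biomarker <- function(x, ...) {
  class(x) <- setdiff(class(x), "eein_biomarker")
  x[, c("p_real", "direction", "min_p_presence", "min_p_survival",
        "is_biomarker")]
}

#' @rdname tidy.eein_biomarker
#' @method glance eein_biomarker
#' @export
glance.eein_biomarker <- function(x, ...) {
  tibble(p.value = x$p_real, is_biomarker = x$is_biomarker,
         direction = x$direction)
}
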