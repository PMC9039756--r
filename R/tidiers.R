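#' Tidy a gene classification
#'
#' @param x An `xcr_classification` object.
#' @param ... Unused.
#' @return The per-gene classification tibble.
#' @export
tidy.xcr_classification <- function(x, ...) {
  as_tibble(unclass_first(x))
}

#' One-row summary of a gene classification
#'
#' @param x An `xcr_classification` object.
#' @param ... Unused.
#' @return A one-row tibble with class counts and the analysis parameters.
#' @export
glance.xcr_classification <- function(x, ...) {
  tb <- as_tibble(unclass_first(x))
  tibble(
    n_genes = nrow(tb),
    n_informative = sum(tb$status != "uninformative"),
    n_escapees = sum(tb$status == "escapee"),
    n_reactivated = sum(tb$status == "reactivated"),
    n_non_reactivated = sum(tb$status == "non_reactivated"),
    alpha = attr(x, "alpha"),
    method = attr(x, "method"),
    treated_condition = attr(x, "treated_condition"),
    control_condition = attr(x, "control_condition")
  )
}

#' Tidy a TAD enrichment result
#' @param x An `xcr_tad_enrichment` object.
#' @param ... Unused.
#' @return The per-TAD tibble.
#' @export
tidy.xcr_tad_enrichment <- function(x, ...) as_tibble(unclass_first(x))

#' One-row summary of a TAD enrichment result
#' @param x An `xcr_tad_enrichment` object.
#' @param ... Unused.
#' @return A one-row tibble: TAD counts, flags and the chromosome-wide
#'   reactivated fraction used as the null.
#' @export
glance.xcr_tad_enrichment <- function(x, ...) {
  tb <- as_tibble(unclass_first(x))
  tibble(
    n_tads = nrow(tb),
    n_enriched = sum(tb$significant_enriched),
    n_depleted = sum(tb$significant_depleted),
    p0 = attr(x, "p0"),
    alpha = attr(x, "alpha")
  )
}

#' Tidy a differential methylation result
#' @param x An `xcr_diff_methylation` object.
#' @param ... Unused.
#' @return The per-region tibble.
#' @export
tidy.xcr_diff_methylation <- function(x, ...) as_tibble(unclass_first(x))

#' One-row summary of a differential methylation result
#' @param x An `xcr_diff_methylation` object.
#' @param ... Unused.
#' @return A one-row tibble with region counts and flags.
#' @export
glance.xcr_diff_methylation <- function(x, ...) {
  tb <- as_tibble(unclass_first(x))
  tibble(
    n_regions = nrow(tb),
    n_tested = sum(!is.na(tb$p_value)),
    n_significantly_lower = sum(tb$significantly_lower, na.rm = TRUE),
    alpha = attr(x, "alpha"),
    control_condition = attr(x, "control_condition"),
    treated_condition = attr(x, "treated_condition")
  )
}

# strip the package's S3 class so dplyr/tibble verbs see a plain tibble
unclass_first <- function(x) {
  class(x) <- setdiff(class(x),
                      c("xcr_classification", "xcr_tad_enrichment",
                        "xcr_diff_methylation"))
  x
}
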