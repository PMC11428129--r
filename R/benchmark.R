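check_property <- function(property) {
  if (!property %in% record_properties) {
    stop(
      "unknown property '", property, "'; expected one of: ",
      paste(record_properties, collapse = ", "),
      call. = FALSE
    )
  }
  property
}

method_block <- function(rs, method) {
  b <- dplyr::filter(rs, .data$method == !!method)
  if (nrow(b) == 0) stop("method not present: ", method, call. = FALSE)
  dplyr::arrange(b, .data$structure)
}

paired_block <- function(rs, method, reference) {
  a <- method_block(rs, method)
  b <- method_block(rs, reference)
  only_a <- setdiff(a$structure, b$structure)
  only_b <- setdiff(b$structure, a$structure)
  if (length(only_a) > 0 || length(only_b) > 0) {
    stop(
      "structure sets differ between ", method, " and ", reference, ": ",
      paste(c(only_a, only_b), collapse = ", "),
      call. = FALSE
    )
  }
  list(method = a, reference = b[match(a$structure, b$structure), ])
}

# native printed precision per property (decimal places)
property_digits <- c(
  dE_eV = 3, delta2pa_au = 0, sigma2pa_GM = 1,
  mu01_D = 3, dmu_D = 3, mu00_D = 3, mu11_D = 3
)

#' Mean absolute error of one method against a reference
#'
#' Unweighted mean over the structures of the absolute difference between a
#' method's property values and the reference method's. This reproduces the
#' MAE rows printed below each functional block of the packaged table when
#' rounded to the property's native precision (3 decimals for eV and D,
#' integer au for the two-photon strength, 1 decimal for GM).
#'
#' @param rs A records tibble (e.g. [builtin_table1()]).
#' @param method,reference Method tokens; both must cover the same
#'   structures.
#' @param property One of `dE_eV`, `delta2pa_au`, `sigma2pa_GM`, `mu01_D`,
#'   `dmu_D`, `mu00_D`, `mu11_D`.
#' @return The MAE in the property's units (unrounded).
#' @examples
#' mae(builtin_table1(), "M11", "RI-CC2", "dE_eV")  # ~0.182
#' @export
mae <- function(rs, method, reference, property) {
  check_property(property)
  p <- paired_block(rs, method, reference)
  mean(abs(p$method[[property]] - p$reference[[property]]))
}

#' Reference-over-method ratio range
#'
#' Minimum and maximum over the structures of `reference / method` for a
#' property — the "underestimation factor" when the method systematically
#' undershoots the reference.
#'
#' @inheritParams mae
#' @return Named numeric `c(min = , max = )`, unrounded; the report layer
#'   rounds to 1 decimal.
#' @examples
#' round(ratio_range(builtin_table1(), "M11", "RI-CC2", "delta2pa_au"), 1)
#' @export
ratio_range <- function(rs, method, reference, property) {
  check_property(property)
  p <- paired_block(rs, method, reference)
  if (any(p$method[[property]] == 0)) {
    stop("zero denominator in ratio for property ", property, call. = FALSE)
  }
  r <- p$reference[[property]] / p$method[[property]]
  c(min = min(r), max = max(r))
}

#' Percent change of a property relative to a baseline structure
#'
#' @inheritParams mae
#' @param structure,baseline Structure tokens, both present under `method`.
#' @return `100 * (value[structure] - value[baseline]) / value[baseline]`.
#' @examples
#' relative_change(builtin_table1(), "RI-CC2", "13-methyl",
#'                 "9,13-dimethyl", "delta2pa_au")  # ~ +29
#' @export
relative_change <- function(rs, method, structure, baseline, property) {
  check_property(property)
  b <- method_block(rs, method)
  vs <- b[[property]][match(structure, b$structure)]
  vb <- b[[property]][match(baseline, b$structure)]
  if (anyNA(c(vs, vb))) {
    stop("structure not present under ", method, call. = FALSE)
  }
  if (vb == 0) stop("zero baseline value", call. = FALSE)
  100 * (vs - vb) / vb
}

#' Rank structures by a property
#'
#' @inheritParams mae
#' @return Character vector of structure tokens in descending property
#'   order; ties broken alphabetically (with a message).
#' @examples
#' ordering(builtin_table1(), "RI-CC2", "delta2pa_au")
#' @export
ordering <- function(rs, method, property) {
  check_property(property)
  b <- method_block(rs, method)
  if (anyDuplicated(b[[property]])) {
    message("ties in ", property, " broken alphabetically")
  }
  b$structure[order(-b[[property]], b$structure)]
}

#' Correlation between quadratic-response and two-state strengths
#'
#' For each structure of a method block, builds the collinear two-state
#' estimate `|mu01|^2 |dmu|^2 / (dE/2)^2` from the tabulated magnitudes
#' (Debye converted to au, eV to hartree) and returns its Pearson
#' correlation with the tabulated two-photon strength. The collinear
#' (angle = 0) assumption is appropriate for quasi-linear charge-transfer
#' chromophores, where the transition dipole and the dipole change both lie
#' along the conjugated chain.
#'
#' @inheritParams mae
#' @return Pearson r.
#' @examples
#' two_state_correlation(builtin_table1(), "RI-CC2")  # > 0.99
#' @export
two_state_correlation <- function(rs, method) {
  b <- method_block(rs, method)
  if (nrow(b) < 3) {
    stop("need at least 3 structures for a correlation", call. = FALSE)
  }
  est <- two_state_estimate(b$mu01_D, b$dmu_D, b$dE_eV)
  stats::cor(est, b$delta2pa_au)
}

# collinear two-state estimate from tabulated magnitudes (D, D, eV) -> au
two_state_estimate <- function(mu01_D, dmu_D, dE_eV) {
  mu01 <- convert_units(mu01_D, "D", "au")
  dmu <- convert_units(dmu_D, "D", "au")
  omega <- convert_units(dE_eV, "eV", "hartree")
  vapply(
    seq_along(mu01),
    function(i) two_state_delta(c(mu01[i], 0, 0), c(dmu[i], 0, 0), omega[i]),
    numeric(1)
  )
}

#' Build the full method-benchmark report
#'
#' Aggregates, against a reference method: per-property MAEs, the
#' reference/method ratio ranges for the two-photon strength and cross
#' section, structure orderings per property, percent changes of every
#' structure vs the native 9,13-dimethyl model, and the quadratic-response
#' vs two-state correlation per method block. Deterministic: the same input
#' always serialises identically.
#'
#' @param rs A records tibble.
#' @param reference Reference method token (default `"RI-CC2"`).
#' @param baseline Baseline structure for relative changes; defaults to the
#'   native 9,13-dimethyl model when present, else the alphabetically first
#'   structure.
#' @return A `tpa_benchmark` object with [tidy()][generics::tidy] /
#'   [glance()][generics::glance] / `autoplot()` methods and fields `mae`
#'   (tibble), `ratios` (tibble), `orderings`, `relative_changes` (tibble),
#'   `correlations` (tibble).
#' @examples
#' rep <- build_report(builtin_table1())
#' tidy(rep)
#' glance(rep)
#' @export
build_report <- function(rs, reference = "RI-CC2", baseline = NULL) {
  methods <- unique(rs$method)
  if (!reference %in% methods) {
    stop("reference method not present: ", reference, call. = FALSE)
  }
  if (is.null(baseline)) {
    baseline <- if (native_structure() %in% rs$structure) {
      native_structure()
    } else {
      sort(unique(rs$structure))[1]
    }
  }
  others <- setdiff(methods, reference)

  mae_tbl <- tidyr::expand_grid(
    method = others, property = record_properties
  )
  mae_tbl$mae <- purrr::map2_dbl(
    mae_tbl$method, mae_tbl$property,
    function(m, p) mae(rs, m, reference, p)
  )
  mae_tbl$mae_printed <- if (nrow(mae_tbl) == 0) {
    numeric(0)
  } else {
    round(mae_tbl$mae, property_digits[mae_tbl$property])
  }

  ratio_tbl <- tidyr::expand_grid(
    method = others, property = c("delta2pa_au", "sigma2pa_GM")
  )
  rr <- purrr::map2(
    ratio_tbl$method, ratio_tbl$property,
    function(m, p) ratio_range(rs, m, reference, p)
  )
  ratio_tbl$ratio_min <- purrr::map_dbl(rr, "min")
  ratio_tbl$ratio_max <- purrr::map_dbl(rr, "max")

  orderings <- purrr::map(
    rlang::set_names(methods),
    function(m) {
      purrr::map(
        rlang::set_names(record_properties),
        function(p) ordering(rs, m, p)
      )
    }
  )

  rel_tbl <- tidyr::expand_grid(
    method = methods,
    structure = setdiff(sort(unique(rs$structure)), baseline),
    property = record_properties
  )
  rel_tbl$percent_change <- purrr::pmap_dbl(
    rel_tbl,
    function(method, structure, property) {
      relative_change(rs, method, structure, baseline, property)
    }
  )

  cor_tbl <- tibble::tibble(
    method = methods,
    pearson_r = purrr::map_dbl(methods, function(m) {
      two_state_correlation(rs, m)
    })
  )

  structure(
    list(
      reference = reference, baseline = baseline,
      mae = mae_tbl, ratios = ratio_tbl, orderings = orderings,
      relative_changes = rel_tbl, correlations = cor_tbl
    ),
    class = "tpa_benchmark"
  )
}

#' @export
print.tpa_benchmark <- function(x, ...) {
  cat("<tpa_benchmark> reference:", x$reference,
    "| baseline structure:", x$baseline, "\n"
  )
  if (nrow(x$mae) > 0) {
    cat("\nMAE vs", x$reference, "(printed precision):\n")
    wide <- tidyr::pivot_wider(
      x$mae[c("method", "property", "mae_printed")],
      names_from = "property", values_from = "mae_printed"
    )
    print(as.data.frame(wide), row.names = FALSE)
  } else {
    cat("single-method record set: no comparisons\n")
  }
  cat("\nQuadratic-response vs two-state correlation:\n")
  print(as.data.frame(x$correlations), row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a benchmark report
#'
#' `tidy()` returns the per-method, per-property MAE table; `glance()`
#' returns one row per method with the strength ratio range and the
#' two-state correlation.
#'
#' @param x A `tpa_benchmark`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tpa_benchmark <- function(x, ...) {
  out <- x$mae
  out$reference <- x$reference
  out[c("method", "reference", "property", "mae", "mae_printed")]
}

#' @rdname tidy.tpa_benchmark
#' @exportS3Method generics::glance
glance.tpa_benchmark <- function(x, ...) {
  ratios <- dplyr::filter(x$ratios, .data$property == "delta2pa_au")
  out <- dplyr::left_join(x$correlations, ratios, by = "method")
  out$reference <- x$reference
  out[c("method", "reference", "ratio_min", "ratio_max", "pearson_r")]
}
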