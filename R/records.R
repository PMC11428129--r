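#' @importFrom rlang .data
NULL

record_cols <- c(
  "method", "structure", "dE_eV", "delta2pa_au", "sigma2pa_GM",
  "mu01_D", "dmu_D", "mu00_D", "mu11_D"
)

record_properties <- c(
  "dE_eV", "delta2pa_au", "sigma2pa_GM", "mu01_D", "dmu_D", "mu00_D", "mu11_D"
)

#' Canonical structure and method labels
#'
#' The seven five-double-bond retinal protonated Schiff base (RPSB5) models
#' are identified by their methylation pattern on the polyene chain; the
#' `(Cs)` / `(twist)` suffix distinguishes the planar and twisted conformers
#' of the doubly and triply methylated analogues. `structure_info()` returns
#' one row per model with its planarity flag and methyl positions;
#' `method_levels()` returns the electronic-structure method tokens, reference
#' first.
#'
#' @return `structure_info()`: a tibble with columns `structure`, `is_planar`
#'   and list-column `methyl_positions`; `method_levels()`: a character vector.
#' @examples
#' structure_info()
#' method_levels()
#' @export
structure_info <- function() {
  tibble::tibble(
    structure = c(
      "9,13-dimethyl", "9-methyl", "13-methyl",
      "9,10-dimethyl (Cs)", "9,10-dimethyl (twist)",
      "9,10,13-trimethyl (Cs)", "9,10,13-trimethyl (twist)"
    ),
    is_planar = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    methyl_positions = list(
      c(9L, 13L), 9L, 13L, c(9L, 10L), c(9L, 10L),
      c(9L, 10L, 13L), c(9L, 10L, 13L)
    )
  )
}

#' @rdname structure_info
#' @export
method_levels <- function() {
  c("RI-CC2", "M11", "MN15", "CAM-B3LYP", "BHandHLYP")
}

#' @rdname structure_info
#' @export
native_structure <- function() "9,13-dimethyl"

# case-insensitive, whitespace-collapsed canonicalisation of structure tokens
normalize_structure <- function(x) {
  key <- tolower(gsub("\\s+", " ", trimws(x)))
  known <- structure_info()$structure
  hit <- match(key, tolower(known))
  out <- ifelse(is.na(hit), trimws(gsub("\\s+", " ", x)), known[hit])
  unknown <- unique(out[is.na(hit)])
  if (length(unknown) > 0) {
    warning(
      "unknown structure label(s), admitted with empty methyl positions: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  out
}

normalize_method <- function(x) {
  key <- tolower(trimws(x))
  known <- method_levels()
  hit <- match(key, tolower(known))
  ifelse(is.na(hit), trimws(x), known[hit])
}

new_recordset <- function(df, provenance = "") {
  out <- tibble::as_tibble(df[record_cols])
  attr(out, "provenance") <- provenance
  class(out) <- c("tpa_records", class(out))
  out
}

#' @export
print.tpa_records <- function(x, ...) {
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) {
    cat("<tpa_records> ", nrow(x), " records | ", prov, "\n", sep = "")
  }
  NextMethod()
}

#' Packaged spectroscopy table for the RPSB5 models
#'
#' Returns the curated table of S1 properties for the seven RPSB5 structures
#' under five methods (the RI-CC2 reference and four TD-DFT functionals):
#' vertical excitation energy (eV), two-photon transition strength (au), 2PA
#' cross section (GM), transition dipole moment, permanent ground- and
#' excited-state dipole moments and their difference (all D). Method-vs-
#' reference mean absolute errors are *not* rows of this table; they are
#' derived quantities, recomputed by [build_report()].
#'
#' @return A `tpa_records` tibble with 35 rows (7 structures x 5 methods) and
#'   columns `method`, `structure`, `dE_eV`, `delta2pa_au`, `sigma2pa_GM`,
#'   `mu01_D`, `dmu_D`, `mu00_D`, `mu11_D`.
#' @examples
#' tab <- builtin_table1()
#' dplyr::filter(tab, method == "RI-CC2")
#' @export
builtin_table1 <- function() {
  path <- system.file("extdata", "table1_rpsb5.csv", package = "rpsb2pa")
  read_records(path, format = "csv", provenance = "packaged RPSB5 S1 table")
}

#' Read and write record tables
#'
#' `read_records()` loads a table of structure-by-method spectroscopic
#' records from CSV or JSON; `write_records()` is its inverse. Units are
#' fixed by the schema (eV, au, GM, D) and never auto-detected. The CSV
#' schema is a header row
#' `method,structure,dE_eV,delta2pa_au,sigma2pa_GM,mu01_D,dmu_D,mu00_D,mu11_D`;
#' the JSON schema is an array of objects with the same nine keys.
#'
#' Structure labels are matched case-insensitively against the canonical
#' tokens of [structure_info()]; unknown labels are admitted with a warning
#' and carry no methyl-position metadata. Duplicate (structure, method) pairs
#' and malformed rows are errors.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @param provenance Free-text provenance attached to the returned set.
#' @param x A records tibble (as from [builtin_table1()]).
#' @return `read_records()`: a `tpa_records` tibble; `write_records()`: the
#'   input, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_records(builtin_table1(), f)
#' identical(dim(read_records(f)), c(35L, 9L))
#' @export
read_records <- function(path, format = c("auto", "csv", "json"),
                         provenance = path) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- if (format == "csv") {
    readr::read_csv(path, col_types = readr::cols(
      method = readr::col_character(),
      structure = readr::col_character(),
      .default = readr::col_double()
    ))
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
  missing_cols <- setdiff(record_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  raw <- raw[record_cols]
  for (i in seq_len(nrow(raw))) {
    vals <- unlist(raw[i, record_properties])
    if (anyNA(vals) || !is.numeric(vals)) {
      bad <- record_properties[is.na(vals)][1]
      stop("malformed row ", i, ": field '", bad, "' is not a number",
        call. = FALSE
      )
    }
  }
  raw$structure <- normalize_structure(raw$structure)
  raw$method <- normalize_method(raw$method)
  dup <- duplicated(raw[c("structure", "method")])
  if (any(dup)) {
    d <- raw[dup, ]
    stop(
      "duplicate (structure, method) pair(s): ",
      paste(paste0("(", d$structure, ", ", d$method, ")"), collapse = "; "),
      call. = FALSE
    )
  }
  new_recordset(raw, provenance = provenance)
}

#' @rdname read_records
#' @export
write_records <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- tibble::as_tibble(as.data.frame(x)[record_cols])
  if (format == "csv") {
    readr::write_csv(df, path)
  } else {
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows")
  }
  invisible(x)
}

#' Validate spectroscopic records against the domain invariants
#'
#' Checks every row for: positive excitation energy, non-negative magnitudes,
#' and the dipole triangle inequality `|mu00 - mu11| <= dmu <= mu00 + mu11`
#' (which must hold because the dipole difference is a vector difference of
#' the two permanent dipoles). Violations are returned as data, one row per
#' violated invariant, never raised as errors.
#'
#' @param x A records tibble.
#' @return A tibble with columns `row`, `structure`, `method`, `invariant`,
#'   `detail`; zero rows when all invariants hold.
#' @examples
#' nrow(validate_records(builtin_table1())) == 0
#' @export
validate_records <- function(x) {
  out <- purrr::map_dfr(seq_len(nrow(x)), function(i) {
    r <- x[i, ]
    v <- list()
    if (!is.na(r$dE_eV) && r$dE_eV <= 0) {
      v <- c(v, list(c(
        "positivity",
        sprintf("dE_eV = %.4g must be > 0", r$dE_eV)
      )))
    }
    for (f in setdiff(record_properties, "dE_eV")) {
      if (!is.na(r[[f]]) && r[[f]] < 0) {
        v <- c(v, list(c(
          "non-negativity",
          sprintf("%s = %.4g must be >= 0", f, r[[f]])
        )))
      }
    }
    # half-ulp slack per printed 3-decimal magnitude: 3 * 0.0005
    slack <- 1.5e-3 + 1e-9
    lo <- abs(r$mu00_D - r$mu11_D)
    hi <- r$mu00_D + r$mu11_D
    if (r$dmu_D < lo - slack || r$dmu_D > hi + slack) {
      v <- c(v, list(c(
        "triangle-inequality",
        sprintf(
          "dmu = %.3f outside [|mu00 - mu11|, mu00 + mu11] = [%.3f, %.3f]",
          r$dmu_D, lo, hi
        )
      )))
    }
    if (length(v) == 0) {
      return(NULL)
    }
    tibble::tibble(
      row = i, structure = r$structure, method = r$method,
      invariant = vapply(v, `[`, "", 1),
      detail = vapply(v, `[`, "", 2)
    )
  })
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble::tibble(
      row = integer(), structure = character(), method = character(),
      invariant = character(), detail = character()
    )
  }
  out
}
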