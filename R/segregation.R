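# Mendelian segregation testing of marker-gene resistance among progeny.
# A hemizygous single dominant locus segregates 3:1 on selfing and 1:1 in a
# backcross to wild type; counts are tested by Pearson's chi-square
# goodness of fit on 1 df, without continuity correction (the correction is
# not what published segregation tables report).

#' Chi-square goodness of fit for segregation records
#'
#' Tests each cross's resistant/susceptible counts against its expected
#' Mendelian ratio with Pearson's chi-square (1 df, no continuity
#' correction). Control crosses with no expected ratio (`ratio` `NA` or
#' `"-"`) pass through untested with `NA` statistics.
#'
#' @param records Tibble with columns `n_resistant`, `n_susceptible` and
#'   `ratio` (strings like `"3:1"`, `"1:1"`, or `"-"`/`NA` for controls);
#'   any other columns (e.g. parent labels) are carried through.
#' @return The input with `chisq`, `df`, `p_value` appended, and
#'   `chisq_2dp`/`p_2dp` — the statistics truncated to two decimals, the
#'   convention used in published segregation tables.
#' @examples
#' chisq_gof(tibble::tibble(n_resistant = 54, n_susceptible = 15,
#'                          ratio = "3:1"))
#' @export
chisq_gof <- function(records) {
  stopifnot(all(c("n_resistant", "n_susceptible", "ratio") %in% names(records)))
  res <- purrr::pmap(
    list(records$n_resistant, records$n_susceptible, records$ratio),
    function(r, s, ratio) {
      if (is.na(ratio) || ratio %in% c("-", "")) {
        return(list(chisq = NA_real_, df = NA_integer_, p_value = NA_real_))
      }
      if (r < 0 || s < 0 || r + s == 0) {
        abort("a tested record needs non-negative counts with a positive total")
      }
      parts <- suppressWarnings(as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]]))
      if (length(parts) != 2 || any(is.na(parts)) || any(parts <= 0)) {
        abort(sprintf("unparseable expected ratio '%s'", ratio))
      }
      expected <- (r + s) * parts / sum(parts)
      if (any(expected < 1)) {
        abort("expected count below 1 in a class; the chi-square approximation does not apply")
      }
      ht <- suppressWarnings(
        stats::chisq.test(c(r, s), p = parts / sum(parts))
      )
      list(chisq = unname(ht$statistic), df = unname(ht$parameter),
           p_value = unname(ht$p.value))
    }
  )
  dplyr::bind_cols(
    records,
    tibble::tibble(
      chisq = purrr::map_dbl(res, "chisq"),
      df = purrr::map_int(res, ~ as.integer(.x$df)),
      p_value = purrr::map_dbl(res, "p_value")
    )
  ) |>
    dplyr::mutate(chisq_2dp = trunc2(.data$chisq), p_2dp = trunc2(.data$p_value))
}

#' Assess consistency with single-locus inheritance
#'
#' Runs [chisq_gof()] and classifies each testable record as consistent with
#' its Mendelian ratio when `p >= alpha`. The overall verdict is
#' `"consistent"` only if every testable record is; controls pass through
#' untested; with no testable records the overall verdict is
#' `"untestable"`.
#'
#' @inheritParams chisq_gof
#' @param alpha Significance level (default 0.05).
#' @return A list with `records` (the per-record table with a `verdict`
#'   column) and `overall` (`"consistent"`, `"inconsistent"` or
#'   `"untestable"`).
#' @export
assess_single_locus <- function(records, alpha = 0.05) {
  out <- chisq_gof(records)
  out$verdict <- dplyr::case_when(
    is.na(out$p_value) ~ "untested",
    out$p_value >= alpha ~ "consistent",
    TRUE ~ "inconsistent"
  )
  testable <- out$verdict != "untested"
  overall <- if (!any(testable)) "untestable"
  else if (all(out$verdict[testable] == "consistent")) "consistent"
  else "inconsistent"
  list(records = out, overall = overall)
}

#' Published tobacco segregation counts
#'
#' The progeny counts of the eleven crosses of the two intragenic
#' chlorsulfuron-resistant tobacco lines (021401-1 and 021401-4): selfings
#' expected 3:1, reciprocal backcrosses to wild type expected 1:1, and two
#' wild-type control crosses with no resistant seedlings. Useful as a
#' real-data fixture for [chisq_gof()].
#'
#' @return A segregation tibble (`ovule_parent`, `pollen_parent`,
#'   `n_resistant`, `n_susceptible`, `ratio`).
#' @export
tobacco_crosses <- function() {
  tibble::tribble(
    ~ovule_parent, ~pollen_parent, ~n_resistant, ~n_susceptible, ~ratio,
    "021401-1",  "021401-1",  54L,  15L, "3:1",
    "021401-4",  "021401-4",  67L,  18L, "3:1",
    "021401-4",  "021401-4",  74L,  23L, "3:1",
    "Wild-type", "021401-1",  28L,  26L, "1:1",
    "Wild-type", "021401-1",  60L,  46L, "1:1",
    "Wild-type", "021401-4",  40L,  41L, "1:1",
    "021401-1",  "Wild-type", 39L,  37L, "1:1",
    "021401-4",  "Wild-type", 42L,  37L, "1:1",
    "021401-4",  "Wild-type", 58L,  52L, "1:1",
    "Wild-type", "Wild-type",  0L, 188L, "-",
    "Wild-type", "Wild-type",  0L,  59L, "-"
  )
}

#' Read and write segregation tables
#'
#' TSV with columns `ovule_parent`, `pollen_parent`, `n_resistant`,
#' `n_susceptible`, `ratio` (e.g. `"3:1"`, `"1:1"`, `"-"`).
#'
#' @param path File path.
#' @param records Segregation tibble (test columns are written when
#'   present).
#' @return A tibble (read) or `path` invisibly (write).
#' @export
read_segregation <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      colClasses = c(ratio = "character")))
}

#' @rdname read_segregation
#' @export
write_segregation <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
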