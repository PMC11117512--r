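#' Paired method measurements
#'
#' @param reference Reference-method values (traditional Doppler ABIs).
#' @param test Test-method values (PWV-system ABIs), aligned with
#'   `reference`.
#' @param labels Optional identifiers (e.g. "subject 3, left").
#' @return Object of class `paired_measurements` with `diffs`
#'   (reference - test) and `means` ((reference + test) / 2).
#' @export
paired_measurements <- function(reference, test, labels = NULL) {
  reference <- as.numeric(reference)
  test <- as.numeric(test)
  if (length(reference) != length(test)) {
    stop("reference and test must have equal length")
  }
  if (any(!is.finite(reference)) || any(!is.finite(test))) {
    stop("paired measurements must be finite")
  }
  if (is.null(labels)) labels <- as.character(seq_along(reference))
  structure(list(labels = labels, reference = reference, test = test,
                 diffs = reference - test, means = (reference + test) / 2),
            class = "paired_measurements")
}

#' Mean absolute error of paired differences
#'
#' @param diffs Numeric vector of between-method differences.
#' @return Mean of `|diffs|`.
#' @export
mae <- function(diffs) {
  if (length(diffs) == 0L) stop("mae of an empty difference vector is undefined")
  mean(abs(diffs))
}

#' Tolerance-band concordance
#'
#' Counts differences within the clinical agreement band (default
#' `|diff| <= 0.1`, closed interval).
#'
#' @param diffs Numeric vector of between-method differences.
#' @param tol Half-width of the agreement band (default 0.1).
#' @return List with `count` and `percent` (100 * count / n).
#' @export
concordance <- function(diffs, tol = 0.1) {
  if (length(diffs) == 0L) stop("concordance of an empty difference vector is undefined")
  if (!is.numeric(tol) || tol <= 0) stop("tol must be positive")
  cnt <- sum(abs(diffs) <= tol)
  list(count = cnt, percent = 100 * cnt / length(diffs))
}

#' Bland-Altman agreement analysis
#'
#' Limits of agreement are `mean(diffs) +/- 1.96 * sd(diffs)`. The SD
#' divisor is selectable: `"POPULATION"` (divisor n, the default) or
#' `"SAMPLE"` (divisor n - 1).
#'
#' @param pairs A `paired_measurements` object (n >= 3).
#' @param sd_mode `"POPULATION"` or `"SAMPLE"`.
#' @return Object of class `bland_altman`: list with `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n_within` (differences inside the closed limits
#'   interval), `n`, `sd_mode`, and the input `pairs`.
#' @export
bland_altman <- function(pairs, sd_mode = c("POPULATION", "SAMPLE")) {
  stopifnot(inherits(pairs, "paired_measurements"))
  sd_mode <- match.arg(sd_mode)
  d <- pairs$diffs
  n <- length(d)
  if (n < 3L) stop("Bland-Altman analysis needs at least 3 pairs")
  m <- mean(d)
  s <- if (sd_mode == "POPULATION") sqrt(mean((d - m)^2)) else stats::sd(d)
  loa <- c(m - 1.96 * s, m + 1.96 * s)
  structure(list(mean_diff = m, sd_diff = s, loa_low = loa[1L],
                 loa_high = loa[2L],
                 n_within = sum(d >= loa[1L] & d <= loa[2L]),
                 n = n, sd_mode = sd_mode, pairs = pairs),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, bias = %.4f, SD (%s) = %.4f\n",
              x$n, x$mean_diff, tolower(x$sd_mode), x$sd_diff))
  cat(sprintf("  limits of agreement [%.4f, %.4f]; %d of %d within\n",
              x$loa_low, x$loa_high, x$n_within, x$n))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences against means with the bias line and limits of agreement.
#' Requires ggplot2.
#'
#' @param ba A `bland_altman` object.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba, title = "Bland-Altman agreement") {
  stopifnot(inherits(ba, "bland_altman"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  df <- data.frame(mean = ba$pairs$means, diff = ba$pairs$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "red") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(title = title, x = "Mean of methods (ABI)",
                  y = "Difference (traditional - system)") +
    ggplot2::theme_minimal()
}

#' Clinical validation report over the 22-subject table
#'
#' Recomputes the method-agreement statistics from the embedded validation
#' table: per-side and per-sex mean absolute error and tolerance-band
#' concordance, and per-side Bland-Altman analyses. Subject 11's censored
#' traditional readings enter numerically as 1.30.
#'
#' @param records A `subject_table` (default: [load_table1()]).
#' @param tol Agreement band half-width (default 0.1).
#' @param sd_mode SD divisor for the Bland-Altman limits.
#' @return Object of class `validation_report`: nested list with elements
#'   `overall`, `right`, `left`, `female`, `male` (each with `n`, `mae`,
#'   `concordance`), sex-by-side concordance breakdowns, and `bland_altman`
#'   results for the right and left pairings.
#' @examples
#' rep <- validation_report()
#' rep$female$mae
#' @export
validation_report <- function(records = load_table1(), tol = 0.1,
                              sd_mode = c("POPULATION", "SAMPLE")) {
  sd_mode <- match.arg(sd_mode)
  if (!inherits(records, "subject_table") || nrow(records) != 22L) {
    stop("validation_report expects the 22-record subject table")
  }
  dr <- records$abi_trad_right - records$abi_sys_right
  dl <- records$abi_trad_left - records$abi_sys_left
  fem <- records$sex == "F"
  summ <- function(d) list(n = length(d), mae = mae(d),
                           concordance = concordance(d, tol))
  lab <- function(side) paste0("subject ", records$subject_id, ", ", side)
  rep <- list(
    tol = tol,
    overall = summ(c(dr, dl)),
    right = summ(dr),
    left = summ(dl),
    female = summ(c(dr[fem], dl[fem])),
    male = summ(c(dr[!fem], dl[!fem])),
    female_right = summ(dr[fem]),
    female_left = summ(dl[fem]),
    male_right = summ(dr[!fem]),
    male_left = summ(dl[!fem]),
    bland_altman = list(
      right = bland_altman(paired_measurements(records$abi_trad_right,
                                               records$abi_sys_right,
                                               lab("right")), sd_mode),
      left = bland_altman(paired_measurements(records$abi_trad_left,
                                              records$abi_sys_left,
                                              lab("left")), sd_mode)
    )
  )
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  fmt <- function(name, s) {
    sprintf("  %-14s n = %2d   MAE = %.4f   within +/-%.2g: %2d (%.2f%%)",
            name, s$n, s$mae, x$tol, s$concordance$count, s$concordance$percent)
  }
  cat("Method agreement: traditional Doppler ABI vs PWV-based system\n")
  for (nm in c("overall", "right", "left", "female", "male",
               "female_right", "female_left", "male_right", "male_left")) {
    cat(fmt(nm, x[[nm]]), "\n")
  }
  cat("Bland-Altman limits of agreement:\n")
  for (side in c("right", "left")) {
    ba <- x$bland_altman[[side]]
    cat(sprintf("  %-6s bias %+.4f, limits [%.4f, %.4f], %d of %d within\n",
                side, ba$mean_diff, ba$loa_low, ba$loa_high, ba$n_within, ba$n))
  }
  invisible(x)
}

#' Serialise a validation report to JSON
#'
#' @param rep A `validation_report`.
#' @return JSON string.
#' @export
validation_report_to_json <- function(rep) {
  stopifnot(inherits(rep, "validation_report"))
  strip_ba <- function(ba) ba[c("mean_diff", "sd_diff", "loa_low", "loa_high",
                                "n_within", "n", "sd_mode")]
  out <- unclass(rep)
  out$bland_altman <- lapply(out$bland_altman, strip_ba)
  as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA))
}
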