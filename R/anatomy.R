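#' Height-driven arterial length model
#'
#' Quadratic models `length = a*H^2 + b*H + c` (metres, `H` = height in
#' metres) for five arterial segments:
#' \describe{
#'   \item{RA, LA}{right/left arm artery, heart to index fingertip}
#'   \item{AR, AL}{right/left leg artery, heart to heel}
#'   \item{PA}{plantar artery, heel to mid-hallux}
#' }
#' The default coefficients were fitted by least squares to measurements on
#' 35 adults of varying height.
#'
#' @param coefficients Numeric 5 x 3 matrix; rows `RA, LA, AR, AL, PA`,
#'   columns `a, b, c`.
#' @return Object of class `length_model`.
#' @export
length_model <- function(coefficients) {
  coefficients <- as.matrix(coefficients)
  if (!all(dim(coefficients) == c(5L, 3L))) {
    stop("coefficients must be a 5 x 3 matrix (segments x (a, b, c))")
  }
  if (is.null(rownames(coefficients))) rownames(coefficients) <- .lm_segments
  if (!identical(rownames(coefficients), .lm_segments)) {
    stop("coefficient rows must be named ", paste(.lm_segments, collapse = ", "))
  }
  colnames(coefficients) <- c("a", "b", "c")
  storage.mode(coefficients) <- "double"
  m <- structure(list(coefficients = coefficients), class = "length_model")
  # evaluated lengths must stay positive over the adult height range
  hh <- seq(1.4, 2.0, by = 0.05)
  for (seg in .lm_segments) {
    if (any(segment_length(m, seg, hh) <= 0)) {
      stop("segment ", seg, " evaluates non-positive on heights [1.4, 2.0] m")
    }
  }
  m
}

.lm_segments <- c("RA", "LA", "AR", "AL", "PA")

#' Default arterial length model
#'
#' @return A `length_model` with the published per-segment quadratic
#'   coefficients.
#' @examples
#' segment_length(default_length_model(), "RA", 1.7)
#' @export
default_length_model <- function() {
  length_model(matrix(c(
    -0.5263, 2.201, -1.311,    # RA
    -0.5018, 2.083, -1.245,    # LA
    -0.3993, 1.967, -0.8949,   # AR
    -0.5543, 2.488, -1.336,    # AL
    -0.2921, 1.055, -0.736     # PA
  ), nrow = 5, byrow = TRUE, dimnames = list(.lm_segments, c("a", "b", "c"))))
}

#' @export
print.length_model <- function(x, ...) {
  cat("<length_model> length = a*H^2 + b*H + c [m]\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

.check_height <- function(height_m) {
  if (!is.numeric(height_m) || any(!is.finite(height_m))) {
    stop("height must be finite numeric (metres)")
  }
  if (any(height_m < 1.0 | height_m > 2.5)) {
    stop("height ", height_m[which(height_m < 1.0 | height_m > 2.5)[1L]],
         " m outside the supported range [1.0, 2.5]; the quadratic model",
         " is unsafe to extrapolate")
  }
}

#' Arterial segment length at a given height
#'
#' @param model A `length_model`.
#' @param segment One of `"RA"`, `"LA"`, `"AR"`, `"AL"`, `"PA"`.
#' @param height_m Height(s) in metres, within `[1.0, 2.5]`.
#' @return Segment length(s) in metres.
#' @export
segment_length <- function(model, segment, height_m) {
  stopifnot(inherits(model, "length_model"))
  segment <- match.arg(segment, .lm_segments)
  .check_height(height_m)
  cf <- model$coefficients[segment, ]
  cf[["a"]] * height_m^2 + cf[["b"]] * height_m + cf[["c"]]
}

#' Composite arterial path lengths for both measurement sites
#'
#' Heart-to-index-finger lengths are the arm segments directly; the
#' heart-to-hallux lengths add the plantar segment to the leg segments:
#' `ARf = AR + PA`, `ALf = AL + PA`.
#'
#' @param model A `length_model`.
#' @param height_m Height in metres.
#' @return Object of class `composite_lengths`: list with `ra_m`, `la_m`
#'   (hand paths) and `arf_m`, `alf_m` (foot paths), all in metres.
#' @export
composite_lengths <- function(model, height_m) {
  pa <- segment_length(model, "PA", height_m)
  structure(list(
    ra_m = segment_length(model, "RA", height_m),
    la_m = segment_length(model, "LA", height_m),
    arf_m = segment_length(model, "AR", height_m) + pa,
    alf_m = segment_length(model, "AL", height_m) + pa
  ), class = "composite_lengths")
}

#' Fit per-segment quadratic length models by least squares
#'
#' Ordinary least-squares fit of `length ~ H^2 + H + 1` per segment.
#' Noise-free data generated from a quadratic are recovered exactly.
#'
#' @param heights Numeric vector of heights in metres (at least 3 distinct
#'   values).
#' @param lengths Data frame or named list with one numeric column per
#'   segment (`RA`, `LA`, `AR`, `AL`, `PA`), aligned with `heights`.
#' @return List with `model` (a `length_model`) and `rss` (named per-segment
#'   residual sums of squares).
#' @export
fit_length_model <- function(heights, lengths) {
  heights <- as.numeric(heights)
  if (length(unique(heights)) < 3L) {
    stop("need at least 3 distinct heights to fit a quadratic")
  }
  lengths <- as.data.frame(lengths)
  missing <- setdiff(.lm_segments, names(lengths))
  if (length(missing) > 0L) {
    stop("lengths is missing segment(s): ", paste(missing, collapse = ", "))
  }
  coef_mat <- matrix(NA_real_, 5, 3, dimnames = list(.lm_segments, c("a", "b", "c")))
  rss <- stats::setNames(numeric(5), .lm_segments)
  for (seg in .lm_segments) {
    y <- as.numeric(lengths[[seg]])
    if (length(y) != length(heights)) {
      stop("segment ", seg, " has ", length(y), " lengths for ",
           length(heights), " heights")
    }
    fit <- stats::lm(y ~ I(heights^2) + heights)
    cf <- stats::coef(fit)
    coef_mat[seg, ] <- c(cf[["I(heights^2)"]], cf[["heights"]], cf[["(Intercept)"]])
    rss[seg] <- sum(stats::residuals(fit)^2)
  }
  list(model = length_model(coef_mat), rss = rss)
}

#' Serialise a length model to JSON
#'
#' @param model A `length_model`.
#' @return JSON string mapping each segment to `[a, b, c]`.
#' @export
length_model_to_json <- function(model) {
  stopifnot(inherits(model, "length_model"))
  lst <- lapply(stats::setNames(.lm_segments, .lm_segments),
                function(s) unname(model$coefficients[s, ]))
  as.character(jsonlite::toJSON(lst, digits = NA))
}

#' Restore a length model from JSON
#'
#' @param json JSON string as produced by [length_model_to_json()].
#' @return A `length_model`.
#' @export
length_model_from_json <- function(json) {
  lst <- jsonlite::fromJSON(json)
  missing <- setdiff(.lm_segments, names(lst))
  if (length(missing) > 0L) {
    stop("JSON is missing segment(s): ", paste(missing, collapse = ", "))
  }
  cf <- do.call(rbind, lapply(lst[.lm_segments], as.numeric))
  rownames(cf) <- .lm_segments
  length_model(cf)
}
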