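#' Variance ratio of multi-predator consumption
#'
#' \deqn{VR = \mathrm{var}\left(\sum_s P_s\right) / \sum_s \mathrm{var}(P_s)}
#' where rows of \code{x} are predator-specific series over the same years.
#' VR = 1 indicates on-average independent predators, VR > 1 synchrony
#' (total variance exceeds the sum of parts), VR < 1 asynchronous,
#' compensating dynamics. Sample variances use the n-1 denominator; VR is
#' invariant to that convention and to common positive rescaling.
#'
#' @param x numeric matrix, predators in rows, years in columns (at least
#'   2 x 2, no missing values).
#' @return VR (>= 0), or NA with a warning when all series are constant.
#' @export
#' @examples
#' variance_ratio(rbind(c(1, 2, 3), c(1, 2, 3)))  # 2
variance_ratio <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("need >= 2 predators and >= 2 years", call. = FALSE)
  }
  if (anyNA(x)) stop("variance ratio window contains gaps", call. = FALSE)
  denom <- sum(apply(x, 1, var))
  if (denom == 0) {
    warning("all predator series constant; variance ratio undefined",
            call. = FALSE)
    return(NA_real_)
  }
  var(colSums(x)) / denom
}

#' Classify a variance ratio into synchrony regimes
#'
#' @param vr variance ratio(s).
#' @param tolerance half-width of the "independent" band around 1
#'   (default 0.1).
#' @return Character: \code{"synchronous"} (VR > 1 + tol),
#'   \code{"asynchronous"} (VR < 1 - tol), else \code{"independent"};
#'   NA stays NA.
#' @export
classify_synchrony <- function(vr, tolerance = 0.1) {
  ifelse(is.na(vr), NA_character_,
         ifelse(vr > 1 + tolerance, "synchronous",
                ifelse(vr < 1 - tolerance, "asynchronous", "independent")))
}

#' Moving-window variance ratios over survey years
#'
#' Computes one variance ratio per window of \code{window} consecutive
#' survey years (not calendar years: surveys may be biennial or triennial),
#' advancing one survey year at a time. Each window is labeled by its first
#' survey year; e.g. survey years 1990, 1993, 1996, 1999, 2001 form the
#' window labeled 1990. Years in which any predator has a gap are masked
#' out before windows are formed.
#'
#' @param series long data frame (year, predator, value); \code{value} may
#'   be NA for gaps. Alternatively a predators x years matrix with year
#'   column names.
#' @param window window length in survey years (default 5).
#' @param tolerance classification band, see [classify_synchrony()].
#' @return Data frame (window_start, VR, PE, classification, years) with
#'   PE = 1 - VR exactly; zero rows (with a warning) when fewer than
#'   \code{window} usable survey years remain.
#' @export
moving_window_variance_ratios <- function(series, window = 5,
                                          tolerance = 0.1) {
  stopifnot(window >= 2)
  if (is.matrix(series)) {
    mat <- series
    yrs <- as.numeric(colnames(series))
  } else {
    stopifnot(all(c("year", "predator", "value") %in% names(series)))
    wide <- tidyr::pivot_wider(series, id_cols = "predator",
                               names_from = "year",
                               values_from = "value")
    mat <- as.matrix(wide[, -1])
    yrs <- as.numeric(colnames(mat))
  }
  ord <- order(yrs)
  mat <- mat[, ord, drop = FALSE]
  yrs <- yrs[ord]
  keep <- colSums(is.na(mat)) == 0
  mat <- mat[, keep, drop = FALSE]
  yrs <- yrs[keep]
  n_win <- length(yrs) - window + 1
  if (n_win < 1) {
    warning("fewer than ", window, " usable survey years; no windows",
            call. = FALSE)
    return(data.frame(window_start = numeric(0), VR = numeric(0),
                      PE = numeric(0), classification = character(0),
                      years = character(0)))
  }
  res <- lapply(seq_len(n_win), function(k) {
    idx <- k:(k + window - 1)
    vr <- suppressWarnings(variance_ratio(mat[, idx, drop = FALSE]))
    data.frame(window_start = yrs[k], VR = vr, PE = 1 - vr,
               classification = classify_synchrony(vr, tolerance),
               years = paste(yrs[idx], collapse = ","))
  })
  dplyr::bind_rows(res)
}

#' Pearson correlation matrix of predator consumption series
#'
#' Pairwise Pearson correlations of predator-specific consumption over
#' years, with two-sided significance tiers at P < 0.1 (*), P < 0.05 (**),
#' and P < 0.001 (***); pairs failing all tiers carry an empty tier.
#' Constant series yield NA correlations for their pairs.
#'
#' @param series long data frame (year, predator, value) or a predators x
#'   years matrix.
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (default \code{"none"}, i.e. unadjusted tests; \code{"holm"}
#'   available).
#' @return List with \code{r} (correlation matrix), \code{p} (p-value
#'   matrix), \code{tier} (character matrix of significance marks).
#' @export
correlation_matrix <- function(series, adjust = "none") {
  if (is.matrix(series)) {
    mat <- series
  } else {
    wide <- tidyr::pivot_wider(series, id_cols = "predator",
                               names_from = "year", values_from = "value")
    mat <- as.matrix(wide[, -1])
    rownames(mat) <- wide$predator
  }
  np <- nrow(mat)
  preds <- rownames(mat) %||% paste0("P", seq_len(np))
  r <- p <- matrix(NA_real_, np, np, dimnames = list(preds, preds))
  for (a in seq_len(np)) {
    for (b in seq_len(np)) {
      ok <- complete.cases(cbind(mat[a, ], mat[b, ]))
      if (a == b) { r[a, b] <- 1; p[a, b] <- 0; next }
      if (sum(ok) < 3 || sd(mat[a, ok]) == 0 || sd(mat[b, ok]) == 0) next
      ct <- cor.test(mat[a, ok], mat[b, ok], method = "pearson")
      r[a, b] <- unname(ct$estimate)
      p[a, b] <- ct$p.value
    }
  }
  if (adjust != "none") {
    up <- p[upper.tri(p)]
    p[upper.tri(p)] <- stats::p.adjust(up, method = adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  tier <- matrix("", np, np, dimnames = list(preds, preds))
  tier[!is.na(p) & p < 0.1] <- "*"
  tier[!is.na(p) & p < 0.05] <- "**"
  tier[!is.na(p) & p < 0.001] <- "***"
  diag(tier) <- ""
  list(r = r, p = p, tier = tier)
}
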