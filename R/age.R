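#' Fit a von Bertalanffy growth curve
#'
#' Nonlinear least squares fit of \eqn{L(t) = L_\infty (1 - e^{-k(t - t_0)})}
#' to age-length pairs.
#'
#' @param age ages (yr).
#' @param length_cm lengths (cm).
#' @return List of class \code{vb_fit}: \code{Linf}, \code{k}, \code{t0},
#'   \code{sigma} (residual SD) and \code{predict(t)}.
#' @export
#' @examples
#' a <- rep(0:6, each = 3)
#' l <- 65 * (1 - exp(-0.25 * (a + 0.5)))
#' fit_von_bertalanffy(a, l)$Linf
fit_von_bertalanffy <- function(age, length_cm) {
  stopifnot(length(age) == length(length_cm))
  if (length(unique(age)) < 3) {
    stop("need at least three distinct ages", call. = FALSE)
  }
  start <- list(Linf = max(length_cm) * 1.1,
                k = 0.3,
                t0 = -0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(length_cm ~ Linf * (1 - exp(-k * (age - t0))),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("von Bertalanffy fit did not converge: ", conditionMessage(e),
           call. = FALSE)
    })
  cf <- coef(fit)
  out <- list(Linf = unname(cf["Linf"]), k = unname(cf["k"]),
              t0 = unname(cf["t0"]),
              sigma = stats::sigma(fit))
  out$predict <- function(t) out$Linf * (1 - exp(-out$k * (t - out$t0)))
  class(out) <- "vb_fit"
  out
}

#' @export
print.vb_fit <- function(x, ...) {
  cat(sprintf("<vb_fit> Linf = %.2f cm, k = %.3f /yr, t0 = %.3f yr ",
              x$Linf, x$k, x$t0),
      sprintf("(residual SD %.3f)\n", x$sigma))
  invisible(x)
}

#' Fit a bias-corrected length-mass relationship
#'
#' Ordinary least squares of \eqn{\ln W} on \eqn{\ln L}. Back-transforming
#' the fitted log-scale mean with a simple exponential underestimates mean
#' mass under lognormal errors, so predictions carry the correction factor
#' \eqn{e^{\hat\sigma^2/2}}.
#'
#' @param length_cm lengths (cm), positive.
#' @param mass_g masses (g), positive.
#' @return List of class \code{lw_fit}: \code{ln_alpha}, \code{beta},
#'   \code{sigma}, \code{correction} and \code{predict(L)} returning
#'   bias-corrected mean mass.
#' @export
fit_length_mass <- function(length_cm, mass_g) {
  stopifnot(length(length_cm) == length(mass_g))
  if (length(length_cm) < 3) stop("need at least three pairs", call. = FALSE)
  if (any(length_cm <= 0) || any(mass_g <= 0)) {
    stop("lengths and masses must be positive", call. = FALSE)
  }
  fit <- lm(log(mass_g) ~ log(length_cm))
  sg <- stats::sigma(fit)
  if (!is.finite(sg)) sg <- 0
  out <- list(ln_alpha = unname(coef(fit)[1]), beta = unname(coef(fit)[2]),
              sigma = sg, correction = exp(sg^2 / 2))
  out$predict <- function(L) {
    exp(out$ln_alpha + out$beta * log(L)) * out$correction
  }
  class(out) <- "lw_fit"
  out
}

#' @export
print.lw_fit <- function(x, ...) {
  cat(sprintf(
    "<lw_fit> ln(a) = %.3f, b = %.3f, sigma = %.3f (correction %.4f)\n",
    x$ln_alpha, x$beta, x$sigma, x$correction))
  invisible(x)
}

#' Reference ages for the prey age classes
#'
#' Mean lengths anchoring the classes 0, 1, 2 and 3+ are evaluated at ages
#' 0.5, 1.5, 2.5 and 4 yr: summer surveys observe fish roughly half a year
#' past their birthday, and 4 yr is a representative age for the open 3+
#' class.
#'
#' @return Named numeric vector of reference ages.
#' @export
age_class_ref_ages <- function() {
  setNames(c(0.5, 1.5, 2.5, 4), age_class_levels())
}

# nearest von Bertalanffy mean length classifier
nearest_age_class <- function(length_cm, growth,
                              ref_ages = age_class_ref_ages()) {
  means <- growth$predict(ref_ages)
  lv <- names(ref_ages)
  lv[max.col(-abs(outer(length_cm, means, "-")))]
}

#' Estimate prey age-class compositions from prey lengths
#'
#' Converts measured prey lengths into year-specific gravimetric
#' proportions of the age classes 0, 1, 2 and 3+ per predator species.
#' Classes are anchored by von Bertalanffy mean lengths-at-age at the
#' reference ages of [age_class_ref_ages()], and prey masses come from the
#' bias-corrected length-mass fit so that proportions are gravimetric.
#'
#' Methods:
#' \describe{
#'  \item{multinomial}{each prey is provisionally classed by nearest mean
#'    length, a multinomial logistic model of class on prey length with a
#'    year effect is fit (mass-weighted), and per-year mean fitted
#'    probabilities give the composition;}
#'  \item{nearest-mean}{gravimetric tabulation of the nearest-mean classes
#'    directly.}
#' }
#' Species-years with no measurable prey take the mean composition over all
#' other years, flagged; a species with no measurable prey in any year is
#' an error.
#'
#' @param prey data frame (species, year, length_cm) of measurable prey;
#'   lengths in cm (convert standard-length mm first, see
#'   [standard_length_to_fork_cm()]).
#' @param growth a [fit_von_bertalanffy()] fit for the prey species.
#' @param length_mass a [fit_length_mass()] fit for the prey species.
#' @param method \code{"multinomial"} (default) or \code{"nearest-mean"}.
#' @param years optional full year set for imputation.
#' @param ref_ages reference ages, see [age_class_ref_ages()].
#' @return Data frame (species, year, age_class, proportion, n_prey,
#'   imputed); proportions form a 4-simplex per species-year.
#' @export
estimate_age_composition <- function(prey, growth, length_mass,
                                     method = c("multinomial",
                                                "nearest-mean"),
                                     years = NULL,
                                     ref_ages = age_class_ref_ages()) {
  method <- match.arg(method)
  stopifnot(all(c("species", "year", "length_cm") %in% names(prey)),
            inherits(growth, "vb_fit"), inherits(length_mass, "lw_fit"))
  prey <- prey[!is.na(prey$length_cm), ]
  if (!nrow(prey)) stop("no measurable prey at all", call. = FALSE)
  prey$age_class <- factor(nearest_age_class(prey$length_cm, growth,
                                             ref_ages),
                           levels = age_class_levels())
  prey$mass <- length_mass$predict(prey$length_cm)
  years <- years %||% sort(unique(prey$year))

  comp_one <- function(d) {
    # gravimetric composition for one species across its observed years
    if (method == "nearest-mean" ||
        length(unique(d$age_class)) < 2L) {
      out <- d %>%
        dplyr::group_by(.data$year, .data$age_class, .drop = FALSE) %>%
        dplyr::summarise(mass = sum(.data$mass), n = dplyr::n(),
                         .groups = "drop_last") %>%
        dplyr::mutate(proportion = .data$mass / sum(.data$mass)) %>%
        dplyr::ungroup()
      out <- out[out$year %in% unique(d$year), ]
      return(as.data.frame(out[, c("year", "age_class", "proportion")]))
    }
    d$year_f <- factor(d$year)
    form <- if (nlevels(d$year_f) > 1) age_class ~ length_cm + year_f
            else age_class ~ length_cm
    fit <- nnet::multinom(form, data = d, weights = d$mass,
                          trace = FALSE, maxit = 500)
    pr <- predict(fit, newdata = d, type = "probs")
    if (is.null(dim(pr))) {  # two observed classes: vector of P(class2)
      lv <- fit$lev
      pr <- cbind(1 - pr, pr)
      colnames(pr) <- lv
    }
    full <- matrix(0, nrow(d), length(age_class_levels()),
                   dimnames = list(NULL, age_class_levels()))
    full[, colnames(pr)] <- pr
    # mass-weighted average of fitted class probabilities per year keeps
    # the composition gravimetric
    yrs_obs <- sort(unique(d$year))
    agg <- t(vapply(yrs_obs, function(yr) {
      i <- d$year == yr
      colSums(full[i, , drop = FALSE] * d$mass[i]) / sum(d$mass[i])
    }, numeric(ncol(full))))
    out <- data.frame(year = rep(yrs_obs, times = ncol(full)),
                      age_class = rep(colnames(full), each = length(yrs_obs)),
                      proportion = as.vector(agg))
    out$proportion <- pmax(out$proportion, 0)
    out %>%
      dplyr::group_by(.data$year) %>%
      dplyr::mutate(proportion = .data$proportion / sum(.data$proportion)) %>%
      dplyr::ungroup() %>%
      as.data.frame()
  }

  res <- lapply(split(prey, prey$species), function(d) {
    sp <- d$species[1]
    comp <- comp_one(d)
    comp$species <- sp
    nprey <- d %>% dplyr::group_by(.data$year) %>%
      dplyr::summarise(n_prey = dplyr::n(), .groups = "drop")
    comp <- dplyr::left_join(comp, nprey, by = "year")
    comp$imputed <- FALSE
    miss <- setdiff(years, unique(comp$year))
    if (length(miss)) {
      m <- comp %>%
        dplyr::group_by(.data$age_class) %>%
        dplyr::summarise(proportion = mean(.data$proportion),
                         .groups = "drop")
      m$proportion <- m$proportion / sum(m$proportion)
      extra <- lapply(miss, function(yr) {
        data.frame(species = sp, year = yr, age_class = m$age_class,
                   proportion = m$proportion, n_prey = 0L, imputed = TRUE)
      })
      comp <- dplyr::bind_rows(c(list(comp), extra))
    }
    comp
  })
  out <- as.data.frame(dplyr::bind_rows(res))
  out$age_class <- as.character(out$age_class)
  out[order(out$species, out$year, match(out$age_class,
                                         age_class_levels())),
      c("species", "year", "age_class", "proportion", "n_prey", "imputed")]
}

#' Convert prey standard length (mm) to fork length (cm)
#'
#' Prey in stomachs are measured as standard length in millimeters; growth
#' and length-mass fits use fork length in centimeters. The default map is
#' the identity on the cm scale (divide by 10); slope and intercept are
#' configurable when a species-specific conversion is known.
#'
#' @param sl_mm standard lengths (mm).
#' @param slope,intercept linear map applied on the cm scale.
#' @return Fork lengths (cm).
#' @export
standard_length_to_fork_cm <- function(sl_mm, slope = 1, intercept = 0) {
  slope * (sl_mm / 10) + intercept
}
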