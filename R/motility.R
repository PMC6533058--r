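# Single-molecule motility and optical-trap statistics: event filtering,
# cumulative-distribution least-squares fits, landing rates, gap analysis,
# detachment-force summaries, group comparisons.

pull_values <- function(data, col, default) {
  if (is.numeric(data)) return(as.numeric(data))
  col <- if (missing(col) || rlang::quo_is_missing(col)) default else col
  if (rlang::is_quosure(col)) {
    out <- rlang::eval_tidy(col, data = data)
  } else {
    if (!col %in% names(data)) abort(sprintf("column `%s` not found", col))
    out <- data[[col]]
  }
  as.numeric(out)
}

#' Filter motility events by minimum duration
#'
#' Kymograph-derived events shorter than `min_frames` frames are discarded
#' (transient binding that cannot be scored as a processive run). Counts of
#' kept and removed events are attached as attributes and reported.
#'
#' @param events tibble with a `duration_frames` column.
#' @param min_frames minimum duration in frames (default 3).
#' @param quiet suppress the kept/removed message.
#' @return the filtered tibble, with attributes `n_kept` and `n_removed`.
#' @export
filter_events <- function(events, min_frames = 3L, quiet = FALSE) {
  if (!"duration_frames" %in% names(events))
    abort("`events` needs a `duration_frames` column")
  keep <- events$duration_frames >= min_frames
  out <- events[keep, , drop = FALSE]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  if (!quiet)
    message(sprintf("kept %d event(s), removed %d (< %d frames)",
                    sum(keep), sum(!keep), min_frames))
  out
}

new_cdf_fit <- function(family, estimate, se, derived_mean, residual, n,
                        extra = list()) {
  structure(
    c(list(
      family = family, estimate = estimate, se = se,
      derived_mean = derived_mean, residual = residual, n = n
    ), extra),
    class = "cdf_fit"
  )
}

#' @export
print.cdf_fit <- function(x, ...) {
  cat(sprintf("<cdf_fit> %s (n = %d)\n", x$family, x$n))
  est <- paste(sprintf("%s = %.4g", names(x$estimate), x$estimate),
               collapse = ", ")
  cat(" ", est, "\n")
  cat(sprintf("  derived mean = %.4g, CDF residual (SS) = %.3g\n",
              x$derived_mean, x$residual))
  invisible(x)
}

#' @export
tidy.cdf_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimate),
    estimate = unname(x$estimate),
    std.error = unname(x$se[names(x$estimate)])
  )
}

#' @export
glance.cdf_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, derived_mean = x$derived_mean,
    residual = x$residual, n = x$n
  )
}

#' @export
autoplot.cdf_fit <- function(object, ...) {
  x <- sort(object$data)
  df <- tibble::tibble(
    x = x, empirical = hazen_positions(length(x)),
    fitted = object$cdf(x)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$empirical), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#b2182b") +
    ggplot2::labs(x = "value", y = "cumulative probability",
                  title = sprintf("%s CDF fit", object$family)) +
    ggplot2::theme_minimal()
}

cdf_ls <- function(x, cdf_fun, par0, lower = NULL) {
  xs <- sort(x)
  p <- hazen_positions(length(xs))
  obj <- function(theta) sum((cdf_fun(xs, theta) - p)^2)
  if (length(par0) == 1L) {
    opt <- optimize(function(lt) obj(exp(lt)),
                    interval = log(c(par0 * 1e-3, par0 * 1e3)))
    list(par = exp(opt$minimum), value = opt$objective)
  } else {
    opt <- optim(par0, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 2000))
    list(par = opt$par, value = opt$value)
  }
}

#' Fit a Gaussian cumulative distribution to velocities
#'
#' Least-squares fit of the Gaussian CDF to the empirical CDF of single-
#' motor velocities (Hazen plotting positions), the standard treatment for
#' kymograph velocity distributions. Reports mean, sd and SEM = sd/sqrt(n).
#'
#' @param data tibble with a `velocity_um_s` column, or a numeric vector.
#' @param velocity tidy-eval column holding velocities (default
#'   `velocity_um_s`).
#' @return a `cdf_fit` object (family `"gaussian"`).
#' @export
fit_velocity_gaussian <- function(data, velocity) {
  v <- pull_values(data, rlang::enquo(velocity), "velocity_um_s")
  if (length(v) < 10) abort("need at least 10 velocities")
  if (sd(v) == 0) abort("zero-variance input")
  fit <- cdf_ls(
    v,
    function(x, th) pnorm(x, mean = th[1], sd = exp(th[2])),
    c(mean(v), log(sd(v)))
  )
  est <- c(mean = fit$par[1], sd = exp(fit$par[2]))
  n <- length(v)
  out <- new_cdf_fit(
    "gaussian", est,
    se = c(mean = est[["sd"]] / sqrt(n), sd = NA_real_),
    derived_mean = est[["mean"]], residual = fit$value, n = n,
    extra = list(
      data = v,
      cdf = function(x) pnorm(x, est[["mean"]], est[["sd"]]),
      sem = est[["sd"]] / sqrt(n)
    )
  )
  out
}

#' Fit a (shifted) exponential distribution to run lengths
#'
#' Least-squares fit of `F(x) = 1 - exp(-(x - offset)/lambda)` to the
#' empirical CDF. The offset accommodates a minimum detectable run; the
#' derived mean run length is `offset + lambda`.
#'
#' @param data tibble with a `run_length_um` column, or a numeric vector.
#' @param run_length tidy-eval column holding run lengths (default
#'   `run_length_um`).
#' @param offset minimum detectable run (um, default 0); all values must
#'   exceed it.
#' @return a `cdf_fit` object (family `"exponential"`).
#' @export
fit_runlength_exponential <- function(data, run_length, offset = 0) {
  x <- pull_values(data, rlang::enquo(run_length), "run_length_um")
  if (length(x) < 10) abort("need at least 10 run lengths")
  if (any(x <= offset)) abort("all run lengths must exceed `offset`")
  if (sd(x) == 0) abort("degenerate fit: all run lengths identical")
  lam0 <- mean(x) - offset
  xs <- sort(x); p <- hazen_positions(length(xs))
  obj <- function(llam) sum((pexp(xs - offset, rate = 1 / exp(llam)) - p)^2)
  opt <- optimize(obj, interval = log(c(lam0 * 1e-3, lam0 * 1e3)))
  lambda <- exp(opt$minimum)
  if (lambda <= 0) abort("non-positive rate estimate")
  n <- length(x)
  new_cdf_fit(
    "exponential", c(lambda = lambda),
    se = c(lambda = lambda / sqrt(n)),
    derived_mean = offset + lambda, residual = opt$objective, n = n,
    extra = list(
      data = x, offset = offset,
      cdf = function(z) pexp(z - offset, rate = 1 / lambda)
    )
  )
}

#' Fit a gamma distribution with fixed scale to run lengths
#'
#' Run-length distributions of motors whose runs are interrupted and
#' resumed are better described by a gamma than an exponential law. The
#' scale parameter theta is fixed at each candidate value (default 1 and
#' 2 um) and the shape k is the only free parameter of a least-squares fit
#' of the gamma CDF to the empirical CDF; the candidate scale with the
#' smaller CDF residual is selected. The expected mean run length is
#' `shape x scale`.
#'
#' @param data tibble with a `run_length_um` column, or a numeric vector.
#' @param run_length tidy-eval column (default `run_length_um`).
#' @param fixed_scales candidate scale values theta (um), default `c(1, 2)`.
#'   To read the fixed values as *rates* instead, pass `1/rates` here.
#' @return a `cdf_fit` object (family `"gamma"`) with `estimate["shape"]`,
#'   the selected `scale`, and `residuals_by_scale` for both candidates.
#' @export
fit_runlength_gamma <- function(data, run_length, fixed_scales = c(1, 2)) {
  x <- pull_values(data, rlang::enquo(run_length), "run_length_um")
  if (length(x) < 10) abort("need at least 10 run lengths")
  if (any(x <= 0)) abort("run lengths must be positive")
  xs <- sort(x); p <- hazen_positions(length(xs))
  fits <- lapply(fixed_scales, function(theta) {
    obj <- function(lk) sum((pgamma(xs, shape = exp(lk), scale = theta) - p)^2)
    k0 <- max(mean(x) / theta, 1e-3)
    opt <- optimize(obj, interval = log(c(k0 * 1e-3, k0 * 1e3)))
    list(shape = exp(opt$minimum), residual = opt$objective)
  })
  res <- vapply(fits, `[[`, numeric(1), "residual")
  if (any(!is.finite(res)))
    abort(sprintf("gamma CDF fit failed; residuals: %s",
                  paste(signif(res, 4), collapse = ", ")))
  best <- which.min(res)
  k <- fits[[best]]$shape
  theta <- fixed_scales[best]
  n <- length(x)
  new_cdf_fit(
    "gamma", c(shape = k, scale = theta),
    se = c(shape = k / sqrt(n), scale = NA_real_),
    derived_mean = k * theta, residual = res[best], n = n,
    extra = list(
      data = x,
      cdf = function(z) pgamma(z, shape = k, scale = theta),
      residuals_by_scale = setNames(res, paste0("scale_", fixed_scales))
    )
  )
}

#' Microtubule landing rate
#'
#' How often motors land on a microtubule to start a processive run,
#' normalized per microtubule length, motor concentration and observation
#' time: `n_events / (length x concentration x time)`, in
#' events um^-1 nM^-1 s^-1. The Poisson standard error is
#' `sqrt(n_events)` over the same denominator.
#'
#' @param n_events number of processive-run initiations observed.
#' @param mt_length_um total microtubule length in the field (um).
#' @param concentration_nM motor concentration (nM).
#' @param time_s observation time (s).
#' @return tibble: `n_events`, `rate`, `se`.
#' @export
landing_rate <- function(n_events, mt_length_um, concentration_nM, time_s) {
  stop_if_not_scalar_number(mt_length_um, "mt_length_um", positive = TRUE)
  stop_if_not_scalar_number(concentration_nM, "concentration_nM", positive = TRUE)
  stop_if_not_scalar_number(time_s, "time_s", positive = TRUE)
  if (n_events < 0) abort("`n_events` must be >= 0")
  denom <- mt_length_um * concentration_nM * time_s
  tibble::tibble(
    n_events = n_events,
    rate = n_events / denom,
    se = sqrt(n_events) / denom
  )
}

#' Displacement deficit during gaps in runs
#'
#' For motors whose kymograph tracks show gaps (intervals where the motor
#' signal pauses or disappears before the run resumes), compares the
#' distance moved during each gap with the distance expected for a motor
#' undergoing constant motility at the event's velocity:
#' `deficit = velocity x gap duration - observed displacement`.
#'
#' @param events tibble with columns `event_id`, `construct`,
#'   `velocity_um_s`, and a `gaps` list-column of tibbles with
#'   `gap_duration_s` and `gap_displacement_um` (events without gaps may
#'   hold `NULL` or empty tibbles).
#' @param pixel_size_um pixel size for the pixel-unit deficit (default
#'   0.16 um, a typical TIRF camera scale).
#' @return per-gap tibble: event id, construct, gap duration, observed and
#'   expected displacement, `deficit_um`, `deficit_px`.
#' @export
gap_displacement_deficit <- function(events, pixel_size_um = 0.16) {
  need <- c("event_id", "velocity_um_s", "gaps")
  if (!all(need %in% names(events)))
    abort("`events` needs columns event_id, velocity_um_s and a `gaps` list-column")
  if (any(is.na(events$velocity_um_s)))
    abort("missing velocity for at least one event")
  rows <- purrr::pmap(
    list(events$event_id,
         events$construct %||% rep("all", nrow(events)),
         events$velocity_um_s, events$gaps),
    function(id, constr, v, g) {
      if (is.null(g) || nrow(g) == 0) return(NULL)
      tibble::tibble(
        event_id = id, construct = constr,
        gap_duration_s = g$gap_duration_s,
        observed_um = g$gap_displacement_um,
        expected_um = v * g$gap_duration_s
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    return(tibble::tibble(
      event_id = integer(), construct = character(),
      gap_duration_s = numeric(), observed_um = numeric(),
      expected_um = numeric(), deficit_um = numeric(), deficit_px = numeric()
    ))
  out$deficit_um <- out$expected_um - out$observed_um
  out$deficit_px <- out$deficit_um / pixel_size_um
  out
}

#' Summarise gap deficits per construct (mean +/- SEM)
#' @param gap_table output of [gap_displacement_deficit()].
#' @return tibble: construct, n_gaps, mean_deficit_um, sem_deficit_um.
#' @export
gap_deficit_summary <- function(gap_table) {
  gap_table |>
    dplyr::group_by(.data$construct) |>
    dplyr::summarise(
      n_gaps = dplyr::n(),
      mean_deficit_um = mean(.data$deficit_um),
      sem_deficit_um = sd(.data$deficit_um) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Detachment-force summary with pairwise t tests vs a reference
#'
#' Per construct, the mean, sd and n of the maximum detachment force per
#' optical-trap event, plus a two-tailed unpaired Student's t test against
#' the reference construct (pooled variance by default; `var_equal = FALSE`
#' gives Welch).
#'
#' @param trap_events tibble with columns `construct` and `max_force_pN`
#'   (forces > 0).
#' @param reference reference construct label (default `"WT"`).
#' @param var_equal pooled-variance t test if `TRUE` (default).
#' @return tibble: construct, n, mean_pN, sd_pN, sem_pN, p_vs_ref (NA for
#'   the reference row).
#' @export
detachment_summary <- function(trap_events, reference = "WT",
                               var_equal = TRUE) {
  need <- c("construct", "max_force_pN")
  if (!all(need %in% names(trap_events)))
    abort("`trap_events` needs columns construct and max_force_pN")
  if (any(trap_events$max_force_pN <= 0)) abort("forces must be > 0")
  counts <- table(trap_events$construct)
  if (any(counts < 2)) abort("every construct needs at least 2 events")
  if (!reference %in% names(counts))
    abort(sprintf("reference construct '%s' not present", reference))
  ref <- trap_events$max_force_pN[trap_events$construct == reference]
  trap_events |>
    dplyr::group_by(.data$construct) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_pN = mean(.data$max_force_pN),
      sd_pN = sd(.data$max_force_pN),
      sem_pN = sd(.data$max_force_pN) / sqrt(dplyr::n()),
      p_vs_ref = if (.data$construct[1] == reference) NA_real_ else
        t.test(.data$max_force_pN, ref, var.equal = var_equal)$p.value,
      .groups = "drop"
    )
}

#' One-way ANOVA across velocity groups
#'
#' @param data tibble with value and group columns.
#' @param value tidy-eval value column (default `velocity_um_s`).
#' @param group tidy-eval group column (default `construct`).
#' @return tibble: statistic (F), df, df_residual, p_value, n_groups.
#' @export
compare_velocities <- function(data, value, group) {
  v <- pull_values(data, rlang::enquo(value), "velocity_um_s")
  g <- group_values(data, rlang::enquo(group))
  if (length(unique(g)) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("each group needs at least 2 values")
  if (sd(v) == 0) abort("degenerate (zero-variance) data")
  fit <- aov(v ~ factor(g))
  a <- anova(fit)
  tibble::tibble(
    statistic = a$`F value`[1],
    df = a$Df[1],
    df_residual = a$Df[2],
    p_value = a$`Pr(>F)`[1],
    n_groups = length(unique(g))
  )
}

group_values <- function(data, quo) {
  if (rlang::quo_is_missing(quo)) {
    if (!"construct" %in% names(data)) abort("column `construct` not found")
    return(as.character(data[["construct"]]))
  }
  as.character(rlang::eval_tidy(quo, data = data))
}

#' Kruskal-Wallis test across run-length groups
#'
#' Rank-based one-way comparison (tie-corrected H statistic, chi-square
#' p-value), the appropriate test for the skewed run-length distributions.
#'
#' @inheritParams compare_velocities
#' @param value tidy-eval value column (default `run_length_um`).
#' @return tibble: statistic (H), df, p_value, n_groups.
#' @export
compare_runlengths <- function(data, value, group) {
  v <- pull_values(data, rlang::enquo(value), "run_length_um")
  g <- group_values(data, rlang::enquo(group))
  if (length(unique(g)) < 2) abort("need at least 2 groups")
  if (sd(v) == 0) abort("all values identical")
  kt <- kruskal.test(v, factor(g))
  tibble::tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value,
    n_groups = length(unique(g))
  )
}
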