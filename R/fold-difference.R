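#' Binomial fraction with standard error
#'
#' `p = k / n` with `SE = sqrt(p (1 - p) / n)`. Vectorised; `n = 0` yields
#' `NA` values flagged undefined.
#'
#' @param k Successes.
#' @param n Totals.
#' @return Tibble (k, n, fraction, se, undefined).
#' @export
#' @examples
#' fraction_with_se(20, 1000)
fraction_with_se <- function(k, n) {
  stopifnot(all(k >= 0 | is.na(k)), all(k <= n | is.na(k) | is.na(n)))
  p <- ifelse(n > 0, k / n, NA_real_)
  tibble(k = k, n = n,
         fraction = p,
         se = ifelse(n > 0, sqrt(p * (1 - p) / n), NA_real_),
         undefined = !(n > 0) | is.na(n))
}

#' Fold difference between a case fraction and a control fraction
#'
#' The deleteriousness statistic: the ratio of the fraction of node-removal
#' mutations (quasi-null among missense, or nonsense among nonsynonymous)
#' in the disease cohort to the same fraction in the non-pathogenic cohort.
#' Call it either with counts (`k_case`, `n_case`, `k_control`,
#' `n_control`) — fraction standard errors are then binomial and the ratio
#' standard error follows by the first-order delta method,
#' `SE(FD) = FD * sqrt((SE_case / f_case)^2 + (SE_control / f_control)^2)`
#' — or directly with two fractions (`f_case`, `f_control`), as when
#' reproducing published fraction pairs, in which case no error is
#' propagated.
#'
#' @param k_case,n_case,k_control,n_control Cohort counts.
#' @param f_case,f_control Fractions (alternative input mode).
#' @param conf_level Confidence level of the normal interval.
#' @return An object of class `fd_result`.
#' @export
#' @examples
#' fold_difference(f_case = 0.193, f_control = 0.065)
#' fold_difference(k_case = 86, n_case = 445, k_control = 537, n_control = 8263)
fold_difference <- function(k_case = NULL, n_case = NULL,
                            k_control = NULL, n_control = NULL,
                            f_case = NULL, f_control = NULL,
                            conf_level = 0.95) {
  if (is.null(f_case)) {
    case <- fraction_with_se(k_case, n_case)
    ctrl <- fraction_with_se(k_control, n_control)
  } else {
    case <- tibble(k = NA_real_, n = NA_real_, fraction = f_case,
                   se = NA_real_, undefined = FALSE)
    ctrl <- tibble(k = NA_real_, n = NA_real_, fraction = f_control,
                   se = NA_real_, undefined = FALSE)
  }
  undefined <- case$undefined | ctrl$undefined |
    (!is.na(ctrl$fraction) & ctrl$fraction == 0)
  fd <- ifelse(undefined, NA_real_, case$fraction / ctrl$fraction)
  se_fd <- ifelse(
    undefined | is.na(case$se) | case$fraction == 0, NA_real_,
    fd * sqrt((case$se / case$fraction)^2 + (ctrl$se / ctrl$fraction)^2))
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    case = case, control = ctrl,
    fd = fd, se = se_fd,
    conf_low = fd - z * se_fd, conf_high = fd + z * se_fd,
    conf_level = conf_level, undefined = undefined
  ), class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat("Fold difference:",
      ifelse(x$undefined, "undefined (control fraction is 0 or n = 0)",
             sprintf("%.3g (case %.3g / control %.3g)",
                     x$fd, x$case$fraction, x$control$fraction)), "\n")
  if (any(!is.na(x$se))) {
    cat(sprintf("  delta-method SE %.3g, %g%% CI [%.3g, %.3g]\n",
                x$se, 100 * x$conf_level, x$conf_low, x$conf_high))
  }
  invisible(x)
}

#' @rdname fold_difference
#' @param x An `fd_result`.
#' @param ... Unused.
#' @export
tidy.fd_result <- function(x, ...) {
  tibble(
    f_case = x$case$fraction, se_case = x$case$se,
    f_control = x$control$fraction, se_control = x$control$se,
    fd = x$fd, se = x$se,
    conf_low = x$conf_low, conf_high = x$conf_high,
    undefined = x$undefined
  )
}

#' @rdname fold_difference
#' @export
glance.fd_result <- function(x, ...) {
  tibble(fd = x$fd, se = x$se, conf_level = x$conf_level,
         undefined = x$undefined)
}

#' Node-removal fold differences from classified calls
#'
#' Computes the two headline statistics from a table of classified,
#' structurally covered mutations: the quasi-null fold difference (fraction
#' of quasi-null among classified missense mutations, case over control) and
#' the nonsense fold difference (fraction of nonsense among nonsynonymous
#' mutations).
#'
#' @param calls Tibble with columns `cohort` (`case`/`control`), `class`
#'   (`missense`/`nonsense`) and, for missense rows, `label`.
#' @return Tibble with one row per statistic (`type`, counts, fractions,
#'   `fd`, `se`, CI bounds).
#' @export
node_removal_fold_differences <- function(calls) {
  count_one <- function(cohort, type) {
    x <- calls[calls$cohort == cohort, , drop = FALSE]
    if (type == "quasi_null") {
      x <- x[x$class == "missense" & !is.na(x$label), , drop = FALSE]
      c(k = sum(x$label == "quasi-null"), n = nrow(x))
    } else {
      c(k = sum(x$class == "nonsense"), n = nrow(x))
    }
  }
  purrr::map(c("quasi_null", "nonsense"), function(type) {
    kc <- count_one("case", type)
    kd <- count_one("control", type)
    fd <- fold_difference(kc[["k"]], kc[["n"]], kd[["k"]], kd[["n"]])
    tidy(fd) |>
      mutate(type = type,
             k_case = kc[["k"]], n_case = kc[["n"]],
             k_control = kd[["k"]], n_control = kd[["n"]],
             .before = 1)
  }) |> purrr::list_rbind()
}
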