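new_fd_sweep <- function(profile, fit, axis, definition) {
  structure(list(profile = profile,
                 slope = if (is.null(fit)) NA_real_ else unname(coef(fit)[2]),
                 intercept = if (is.null(fit)) NA_real_ else unname(coef(fit)[1]),
                 residuals = if (is.null(fit)) numeric(0) else unname(fit$residuals),
                 axis = axis, definition = definition),
            class = "fd_sweep")
}

sweep_fit <- function(profile) {
  ok <- is.finite(profile$fd)
  if (sum(ok) < 2) return(NULL)
  lm(fd ~ threshold, data = profile[ok, ])
}

#' Fold difference versus folding delta-delta-G threshold
#'
#' For each threshold `t` on the grid, recomputes the fold difference of the
#' quasi-null predicate `folding_ddg >= t` (with the additional burial
#' condition `rsa <= rsa_cutoff` under the `"ddg_rsa"` definition) between
#' the case and control missense sets, then fits an ordinary-least-squares
#' line through the defined points of the (threshold, fold difference)
#' profile. Numerator counts are non-increasing in the threshold by
#' construction.
#'
#' @param case,control Tibbles of missense mutations with `folding_ddg` and,
#'   for the `"ddg_rsa"` definition, `rsa`.
#' @param thresholds Increasing threshold grid (kcal/mol), default 1-45.
#' @param definition `"ddg_only"` or `"ddg_rsa"`.
#' @param rsa_cutoff Burial cutoff for `"ddg_rsa"`.
#' @param weighted Weight the fit by per-point inverse squared fold
#'   difference standard errors (default unweighted).
#' @return An object of class `fd_sweep`: `profile` tibble (threshold,
#'   k_case, n_case, k_control, n_control, fd, se), `slope`, `intercept`,
#'   `residuals`.
#' @export
ddg_sweep <- function(case, control, thresholds = 1:45,
                      definition = c("ddg_only", "ddg_rsa"),
                      rsa_cutoff = 0.25, weighted = FALSE) {
  definition <- match.arg(definition)
  stopifnot(all(diff(thresholds) > 0))
  pred <- function(df, t) {
    hit <- df$folding_ddg >= t
    if (definition == "ddg_rsa") hit <- hit & df$rsa <= rsa_cutoff
    sum(hit, na.rm = TRUE)
  }
  profile <- purrr::map(thresholds, function(t) {
    fd <- fold_difference(pred(case, t), nrow(case),
                          pred(control, t), nrow(control))
    tidy(fd) |>
      transmute(threshold = t,
                k_case = pred(case, t), n_case = nrow(case),
                k_control = pred(control, t), n_control = nrow(control),
                fd = .data$fd, se = .data$se)
  }) |> purrr::list_rbind()
  fit <- if (weighted) {
    ok <- is.finite(profile$fd) & is.finite(profile$se) & profile$se > 0
    if (sum(ok) < 2) NULL
    else lm(fd ~ threshold, data = profile[ok, ], weights = 1 / profile$se[ok]^2)
  } else {
    sweep_fit(profile)
  }
  new_fd_sweep(profile, fit, axis = "folding_ddg", definition = definition)
}

#' Fold difference versus RSA cutoff
#'
#' Analogue of [ddg_sweep()] sweeping the burial cutoff from full exposure
#' (1.0) towards complete burial (0.0) with predicate `rsa <= cutoff`,
#' optionally combined with the folding-instability condition
#' (`"rsa_ddg"`).
#'
#' @param case,control Missense tibbles with `rsa` (and `folding_ddg` for
#'   `"rsa_ddg"`).
#' @param cutoffs Decreasing RSA cutoff grid.
#' @param definition `"rsa_ddg"` or `"rsa_only"`.
#' @param ddg_threshold Folding threshold for `"rsa_ddg"`.
#' @return An object of class `fd_sweep` (threshold column holds the RSA
#'   cutoff).
#' @export
rsa_sweep <- function(case, control, cutoffs = seq(1, 0, by = -0.05),
                      definition = c("rsa_ddg", "rsa_only"),
                      ddg_threshold = 2) {
  definition <- match.arg(definition)
  stopifnot(all(diff(cutoffs) < 0))
  pred <- function(df, cut) {
    hit <- df$rsa <= cut
    if (definition == "rsa_ddg") hit <- hit & df$folding_ddg >= ddg_threshold
    sum(hit, na.rm = TRUE)
  }
  profile <- purrr::map(cutoffs, function(cut) {
    fd <- fold_difference(pred(case, cut), nrow(case),
                          pred(control, cut), nrow(control))
    tidy(fd) |>
      transmute(threshold = cut,
                k_case = pred(case, cut), n_case = nrow(case),
                k_control = pred(control, cut), n_control = nrow(control),
                fd = .data$fd, se = .data$se)
  }) |> purrr::list_rbind()
  fit <- {
    ok <- is.finite(profile$fd)
    if (sum(ok) < 2) NULL else lm(fd ~ threshold, data = profile[ok, ])
  }
  new_fd_sweep(profile, fit, axis = "rsa", definition = definition)
}

#' @export
print.fd_sweep <- function(x, ...) {
  cat(sprintf("Fold-difference sweep over %s (%s): %d grid points\n",
              x$axis, x$definition, nrow(x$profile)))
  if (is.finite(x$slope)) {
    cat(sprintf("  best fit: y = %.3fx + %.3f\n", x$slope, x$intercept))
  } else {
    cat("  fit omitted (fewer than two defined points)\n")
  }
  invisible(x)
}

#' @rdname ddg_sweep
#' @param x An `fd_sweep`.
#' @param ... Unused.
#' @export
tidy.fd_sweep <- function(x, ...) x$profile

#' @rdname ddg_sweep
#' @export
glance.fd_sweep <- function(x, ...) {
  tibble(axis = x$axis, definition = x$definition,
         slope = x$slope, intercept = x$intercept,
         n_points = sum(is.finite(x$profile$fd)))
}
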