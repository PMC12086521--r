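#' Configuration for the synthetic study generator
#'
#' Bundles every tunable of the synthetic-data module: proteome size,
#' interaction count and interface geometry, cohort sizes, the programmed
#' interface-placement probabilities, per-cohort folding and binding
#' delta-delta-G distributions (shifted log-normals), nonsense fractions,
#' the control-cohort allele-frequency power law, and the indel perturbation
#' applied to the variant-source ("RefSeq-like") copies of the canonical
#' sequences.
#'
#' The defaults emulate the statistical structure of the real study's
#' HI-union-based cohorts: 722 disease and 8428 control nonsynonymous
#' records, 38.4% of disease-cohort and 2.0% of control-cohort
#' nonsynonymous mutations are nonsense, and the folding delta-delta-G
#' log-normals are calibrated so that, after edgetic precedence, 19.3% of
#' disease and 6.5% of control missense mutations are quasi-null at the
#' 2 kcal/mol folding threshold. Control allele frequencies follow a
#' truncated power law on [1.5625e-4, 0.5], the observed AF floor of the
#' non-pathogenic catalog.
#'
#' @param n_proteins Number of canonical proteins in the toy proteome.
#' @param length_range Integer length-2 vector, residue-count interval for
#'   protein lengths (inclusive).
#' @param n_ppis Number of binary interactions (each gets one dimer
#'   structure).
#' @param interface_size Programmed number of contact residues per side of
#'   each dimer interface.
#' @param n_case_mut,n_control_mut Catalog sizes for the disease (case) and
#'   non-pathogenic (control) cohorts.
#' @param p_interface_case,p_interface_control Probability that a missense
#'   mutation is placed on an interfacial residue.
#' @param ddg_fold_params_case,ddg_fold_params_control Named numeric vectors
#'   `c(meanlog=, sdlog=, shift=)` of the folding delta-delta-G distribution
#'   (kcal/mol) per cohort; values are `shift + rlnorm(meanlog, sdlog)`.
#' @param ddg_bind_params Same parameterisation for binding delta-delta-G at
#'   interface placements.
#' @param nonsense_frac_case,nonsense_frac_control Probability that a
#'   catalog record is nonsense rather than missense.
#' @param af_exponent Exponent of the truncated power-law density
#'   `f(x) ~ x^-af_exponent` for control allele frequencies.
#' @param af_range Support of the allele-frequency power law.
#' @param indel_rate Per-residue probability of starting an indel when
#'   deriving the variant-source copy of a canonical sequence.
#' @param max_indel_len Maximum indel length (residues).
#' @param seed Integer seed; identical configs give bit-identical outputs.
#' @return A list of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_proteins = 6, n_ppis = 4, seed = 1)
#' cfg$interface_size
synthetic_config <- function(n_proteins = 60,
                             length_range = c(80L, 150L),
                             n_ppis = 40,
                             interface_size = 8,
                             n_case_mut = 722,
                             n_control_mut = 8428,
                             p_interface_case = 0.20,
                             p_interface_control = 0.10,
                             ddg_fold_params_case = lnorm_tail_params(
                               p_tail = 0.193 / (1 - 0.20 * 0.588),
                               at = 2, sdlog = 1.2),
                             ddg_fold_params_control = lnorm_tail_params(
                               p_tail = 0.065 / (1 - 0.10 * 0.588),
                               at = 2, sdlog = 1.2),
                             ddg_bind_params = c(meanlog = 0, sdlog = 1,
                                                 shift = 0),
                             nonsense_frac_case = 0.384,
                             nonsense_frac_control = 0.02,
                             af_exponent = 1.5,
                             af_range = c(1.5625e-4, 0.5),
                             indel_rate = 0,
                             max_indel_len = 3,
                             seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    length_range = as.integer(length_range),
    n_ppis = as.integer(n_ppis),
    interface_size = as.integer(interface_size),
    n_case_mut = as.integer(n_case_mut),
    n_control_mut = as.integer(n_control_mut),
    p_interface_case = p_interface_case,
    p_interface_control = p_interface_control,
    ddg_fold_params_case = complete_ddg_params(ddg_fold_params_case),
    ddg_fold_params_control = complete_ddg_params(ddg_fold_params_control),
    ddg_bind_params = complete_ddg_params(ddg_bind_params),
    nonsense_frac_case = nonsense_frac_case,
    nonsense_frac_control = nonsense_frac_control,
    af_exponent = af_exponent,
    af_range = af_range,
    indel_rate = indel_rate,
    max_indel_len = as.integer(max_indel_len),
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

complete_ddg_params <- function(p) {
  out <- c(meanlog = 0, sdlog = 1, shift = 0)
  out[names(p)] <- p
  out
}

validate_synthetic_config <- function(cfg) {
  probs <- c(cfg$p_interface_case, cfg$p_interface_control,
             cfg$nonsense_frac_case, cfg$nonsense_frac_control,
             cfg$indel_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]", class = "edgotyper_config_error")
  }
  counts <- c(cfg$n_proteins, cfg$n_ppis, cfg$n_case_mut, cfg$n_control_mut)
  if (any(counts <= 0)) {
    abort("counts must be positive", class = "edgotyper_config_error")
  }
  if (cfg$length_range[1] < 30 || diff(cfg$length_range) < 0) {
    abort("length_range must be an increasing interval with minimum >= 30",
          class = "edgotyper_config_error")
  }
  if (cfg$n_ppis > choose(cfg$n_proteins, 2)) {
    abort("n_ppis exceeds the number of distinct protein pairs",
          class = "edgotyper_config_error")
  }
  invisible(cfg)
}

#' Log-normal parameters pinned to a tail probability
#'
#' Convenience for calibrating a folding delta-delta-G log-normal so that
#' `P(X >= at) = p_tail` at a given `sdlog`: returns
#' `meanlog = log(at) - sdlog * qnorm(1 - p_tail)`.
#'
#' @param p_tail Target upper-tail probability at `at`.
#' @param at Threshold (kcal/mol) where the tail is pinned.
#' @param sdlog Log-scale standard deviation.
#' @param shift Additive shift of the distribution.
#' @return Named numeric vector `c(meanlog, sdlog, shift)`.
#' @export
lnorm_tail_params <- function(p_tail, at = 2, sdlog = 1.2, shift = 0) {
  stopifnot(p_tail > 0, p_tail < 1, at > shift)
  c(meanlog = log(at - shift) - sdlog * qnorm(1 - p_tail),
    sdlog = sdlog, shift = shift)
}

#' Sample folding or binding delta-delta-G values
#'
#' Draws from the generator's shifted log-normal severity model,
#' `shift + rlnorm(meanlog, sdlog)` (kcal/mol, positive = destabilising).
#'
#' @param n Number of draws.
#' @param params Named vector `c(meanlog, sdlog, shift)`.
#' @return Numeric vector of delta-delta-G values.
#' @export
sample_ddg <- function(n, params) {
  params <- complete_ddg_params(params)
  params[["shift"]] + stats::rlnorm(n, params[["meanlog"]], params[["sdlog"]])
}

# upper-tail probability of the shifted log-normal severity model
ddg_tail_prob <- function(t, params) {
  params <- complete_ddg_params(params)
  stats::plnorm(pmax(t - params[["shift"]], 0),
                params[["meanlog"]], params[["sdlog"]],
                lower.tail = FALSE)
}

#' Sample allele frequencies from a truncated power law
#'
#' Inverse-CDF sampling from the density `f(x) ~ x^-exponent` truncated to
#' `range`, the generator's model of the control cohort's allele-frequency
#' spectrum (rare variants dominate).
#'
#' @param n Number of draws.
#' @param exponent Power-law exponent (> 0).
#' @param range Length-2 support, default the catalog floor `1.5625e-4` to
#'   `0.5`.
#' @return Numeric vector of allele frequencies.
#' @export
sample_allele_frequency <- function(n, exponent = 1.5,
                                    range = c(1.5625e-4, 0.5)) {
  lo <- range[1]; hi <- range[2]
  u <- runif(n)
  if (abs(exponent - 1) < 1e-12) {
    exp(log(lo) + u * (log(hi) - log(lo)))
  } else {
    a <- 1 - exponent
    (lo^a + u * (hi^a - lo^a))^(1 / a)
  }
}
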