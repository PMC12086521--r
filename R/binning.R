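AF_BIN_LABELS <- c("<0.1%", "0.1%-1.0%", "1.0%-10.0%", ">10.0%")

#' Allele-frequency bin of a variant
#'
#' Assigns allele frequencies to the four spectrum bins `<0.1%`,
#' `0.1%-1.0%`, `1.0%-10.0%`, `>10.0%`, left-closed / right-open at the
#' internal boundaries (0.001, 0.01, 0.1). Missing frequencies yield `NA`
#' and are excluded from frequency analyses.
#'
#' @param af Numeric allele frequencies in (0, 1].
#' @return Factor with the four bin labels.
#' @export
#' @examples
#' af_bin(c(0.0005, 0.001, 0.3426))
af_bin <- function(af) {
  cut(af, breaks = c(0, 0.001, 0.01, 0.1, Inf), labels = AF_BIN_LABELS,
      right = FALSE)
}

#' Node-removal fractions across allele-frequency bins
#'
#' For the control cohort, computes per-bin fractions of quasi-null variants
#' (among missense) and nonsense variants (among nonsynonymous) with
#' binomial standard errors.
#'
#' @param calls Classified control-cohort tibble with `class`, `label`,
#'   `af`.
#' @return An object of class `binned_result`: tibble with one row per
#'   (bin, type), counts, fraction, se.
#' @export
af_fraction_profile <- function(calls) {
  x <- calls |>
    filter(!is.na(.data$af)) |>
    mutate(bin = af_bin(.data$af))
  per_bin <- purrr::map(levels(x$bin), function(b) {
    xb <- x[x$bin == b, , drop = FALSE]
    miss <- xb[xb$class == "missense" & !is.na(xb$label), , drop = FALSE]
    bind_rows(
      fraction_with_se(sum(miss$label == "quasi-null"), nrow(miss)) |>
        mutate(bin = b, type = "quasi_null"),
      fraction_with_se(sum(xb$class == "nonsense"), nrow(xb)) |>
        mutate(bin = b, type = "nonsense")
    )
  }) |> purrr::list_rbind() |>
    mutate(bin = factor(.data$bin, levels = AF_BIN_LABELS)) |>
    select("bin", "type", "k", "n", "fraction", "se", "undefined")
  structure(list(bins = per_bin, axis = "allele_frequency"),
            class = "binned_result")
}

#' Positional distribution of node-removal mutations
#'
#' Counts mutations falling in the first region of their protein — the first
#' half (`window = "half"`) or the first 5% (`window = "tail5"`) — against
#' the complementary last region. The first region is positions
#' `1..ceiling(L * w)`; the last region is positions `> L - ceiling(L * w)`
#' (for the half window the two regions partition the protein, the midpoint
#' of odd-length proteins counting as first-half).
#'
#' @param mutations Tibble with `canonical_pos`, `protein_length`, `cohort`,
#'   and a mutation `type` column (e.g. `quasi_null` / `nonsense`).
#' @param window `"half"` or `"tail5"`.
#' @return Tibble per (cohort, type): counts and percentages in the first
#'   and last regions.
#' @export
position_distribution <- function(mutations, window = c("half", "tail5")) {
  window <- match.arg(window)
  w <- if (window == "half") 0.5 else 0.05
  mutations |>
    mutate(cut = ceiling(.data$protein_length * w),
           first_region = .data$canonical_pos <= .data$cut,
           # the two halves partition the protein (odd-length midpoints
           # count as first-half); the 5% windows are symmetric tails
           last_region = if (window == "half") !.data$first_region
                         else .data$canonical_pos >
                           .data$protein_length - .data$cut) |>
    group_by(.data$cohort, .data$type) |>
    summarise(n = n(),
              n_first = sum(.data$first_region),
              n_last = sum(.data$last_region),
              .groups = "drop") |>
    mutate(pct_first = 100 * .data$n_first / .data$n,
           pct_last = 100 * .data$n_last / .data$n)
}

round_mode <- function(x, digits = 2) {
  r <- round(x, digits)
  tb <- table(r)
  as.numeric(names(tb)[which.max(tb)])
}

#' Coverage-ratio confounder analysis
#'
#' Tests whether fold differences are confounded by partial structural
#' coverage. Each node-removal mutation carries the coverage ratio
#' `r = model length / protein length` of its protein's model; mutations
#' are binned into (0, 0.2], (0.2, 0.4], (0.4, 0.6], (0.6, 0.8],
#' (0.8, 1.0] (right-closed) and the fold difference is recomputed per bin
#' for quasi-null and nonsense types, together with per-bin mean folding
#' delta-delta-G and mean model length. Global mean / median / mode (mode
#' after rounding to 2 decimals) of the three length ratios —
#' canonical/source, source/canonical, and model/canonical — are reported
#' alongside.
#'
#' @param mutations Tibble with `cohort`, a node-removal `type` column
#'   (`quasi_null` / `nonsense`), `model_length`, `protein_length`,
#'   `source_length`, and `folding_ddg` (NA for nonsense).
#' @return A list of class `coverage_confounder`: `bins` (per-bin tibble
#'   with counts, fd, mean folding ddG, mean model length), `ratios`
#'   (mean/median/mode of the three length ratios).
#' @export
coverage_confounder <- function(mutations) {
  stopifnot(all(mutations$protein_length > 0),
            all(mutations$source_length > 0))
  x <- mutations |>
    mutate(r = .data$model_length / .data$protein_length,
           bin = cut(.data$r, breaks = seq(0, 1, by = 0.2), right = TRUE))

  bins <- purrr::map(levels(x$bin), function(b) {
    xb <- x[!is.na(x$bin) & x$bin == b, , drop = FALSE]
    purrr::map(unique(mutations$type), function(ty) {
      kc <- sum(xb$cohort == "case" & xb$type == ty)
      nc <- sum(x$cohort == "case" & x$type == ty)
      kd <- sum(xb$cohort == "control" & xb$type == ty)
      nd <- sum(x$cohort == "control" & x$type == ty)
      fdres <- fold_difference(kc, nc, kd, nd)
      tibble(bin = b, type = ty,
             k_case = kc, k_control = kd,
             fd = fdres$fd, se = fdres$se,
             mean_folding_ddg = mean(xb$folding_ddg[xb$type == ty],
                                     na.rm = TRUE),
             mean_model_length = mean(xb$model_length[xb$type == ty]))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  ratio_summary <- function(v, name) {
    tibble(ratio = name, mean = mean(v), median = median(v),
           mode = round_mode(v))
  }
  ratios <- bind_rows(
    ratio_summary(x$protein_length / x$source_length, "canonical_over_source"),
    ratio_summary(x$source_length / x$protein_length, "source_over_canonical"),
    ratio_summary(x$model_length / x$protein_length, "model_over_canonical")
  )
  structure(list(bins = bins, ratios = ratios), class = "coverage_confounder")
}

#' Mean substitution score per edgotype class
#'
#' Arithmetic mean of the BLOSUM62 score of the amino-acid substitution in
#' each edgotype class; more disruptive classes are expected to carry lower
#' (less conservative) means.
#'
#' @param calls Classified missense tibble with `ref`, `alt`, `label`.
#' @return Tibble (label, n, mean_blosum62); classes absent from the input
#'   are flagged with `n = 0` and `NA` mean.
#' @export
mean_blosum_by_edgotype <- function(calls) {
  x <- calls |>
    filter(!is.na(.data$label)) |>
    mutate(score = blosum62(.data$ref, .data$alt))
  tibble(label = c("quasi-wildtype", "edgetic", "quasi-null")) |>
    left_join(x |> group_by(.data$label) |>
                summarise(n = n(), mean_blosum62 = mean(.data$score)),
              by = "label") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
}

#' Fold differences stratified by protein category
#'
#' Recomputes a node-removal fold difference within each protein category
#' (for example transcription factors versus the rest, or housekeeping
#' versus the rest) and per structural interactome, plus a pooled "overall"
#' estimate across interactomes obtained by summing numerators and
#' denominators after removing duplicate (accession, position, ref, alt)
#' records.
#'
#' @param calls Classified tibble with `si`, `cohort`, `class`, `label`,
#'   `canonical_acc`, `canonical_pos`, `ref`, `alt`.
#' @param categories Named list of accession vectors defining the
#'   categories; accessions outside every category are ignored (supply the
#'   complement explicitly if wanted).
#' @param type `"quasi_null"` or `"nonsense"`.
#' @return Tibble per (category, si) and per category pooled
#'   (`si = "overall"`), with counts and the fold difference.
#' @export
stratified_fold_difference <- function(calls, categories,
                                       type = c("quasi_null", "nonsense")) {
  type <- match.arg(type)
  counts <- function(x) {
    if (type == "quasi_null") {
      x <- x[x$class == "missense" & !is.na(x$label), , drop = FALSE]
      k <- sum(x$label == "quasi-null")
    } else {
      k <- sum(x$class == "nonsense")
    }
    c(k = k, n = nrow(x))
  }
  one <- function(x, category, si_name) {
    kc <- counts(x[x$cohort == "case", , drop = FALSE])
    kd <- counts(x[x$cohort == "control", , drop = FALSE])
    fdres <- fold_difference(kc[["k"]], kc[["n"]], kd[["k"]], kd[["n"]])
    tibble(category = category, si = si_name,
           k_case = kc[["k"]], n_case = kc[["n"]],
           k_control = kd[["k"]], n_control = kd[["n"]],
           fd = fdres$fd, se = fdres$se, undefined = fdres$undefined)
  }
  purrr::imap(categories, function(accs, category) {
    x <- calls[calls$canonical_acc %in% accs, , drop = FALSE]
    per_si <- purrr::map(unique(x$si),
                         function(s) one(x[x$si == s, , drop = FALSE],
                                         category, s)) |>
      purrr::list_rbind()
    pooled <- x |>
      distinct(.data$canonical_acc, .data$canonical_pos, .data$ref,
               .data$alt, .keep_all = TRUE)
    bind_rows(per_si, one(pooled, category, "overall"))
  }) |> purrr::list_rbind()
}

#' Categorise edgetic mutations by the nature of the disrupted edges
#'
#' `E1` when every disrupted interaction carries the first label (for
#' example transient, or tissue-specific), `E2` when every disrupted
#' interaction carries the second label (permanent / non-tissue-specific),
#' and `E3` otherwise — mixed sets and interactions with no clear label both
#' fall through to `E3`.
#'
#' @param calls Classified tibble with `label` and list-column
#'   `disrupted_ppis`.
#' @param edge_labels Tibble (ppi_id, edge_class) with `edge_class` in
#'   `class1` / `class2` / anything else (treated as undefined).
#' @param class1,class2 The two defined edge classes (defaults `transient`,
#'   `permanent`).
#' @return Input tibble plus `edgetic_category` (`NA` for non-edgetic
#'   rows).
#' @export
categorize_edgetic <- function(calls, edge_labels,
                               class1 = "transient", class2 = "permanent") {
  lab <- setNames(edge_labels$edge_class, edge_labels$ppi_id)
  calls |>
    mutate(edgetic_category = purrr::map2_chr(
      .data$label, .data$disrupted_ppis,
      function(l, ppis) {
        if (is.na(l) || l != "edgetic") return(NA_character_)
        cls <- unname(lab[ppis])
        if (all(!is.na(cls) & cls == class1)) "E1"
        else if (all(!is.na(cls) & cls == class2)) "E2"
        else "E3"
      }))
}
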