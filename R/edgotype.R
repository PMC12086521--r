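#' Classify mutation location (interfacial or not)
#'
#' A mutation is at an interfacial residue (`IR`) when its canonical
#' position lies in the union of its protein's mapped interfacial residue
#' sets across all the protein's structurally resolved interactions;
#' otherwise it is non-interfacial (`NIR`). Proteins with no interactions
#' (structural-proteome mode) yield `NIR` by the empty-union convention.
#'
#' @param mutations Tibble with `id`, `canonical_acc`, `canonical_pos`.
#' @param si Structural interactome (its `interfaces` table is used).
#' @return Input tibble plus a `location` column.
#' @export
classify_location <- function(mutations, si) {
  key <- paste(si$interfaces$accession, si$interfaces$position)
  mutations |>
    mutate(location = ifelse(
      paste(.data$canonical_acc, .data$canonical_pos) %in% key, "IR", "NIR"))
}

#' Apply the edgotype decision tree
#'
#' Implements the classification cascade for missense mutations: an
#' interfacial mutation disrupting at least one interaction (binding
#' delta-delta-G strictly greater than `binding_threshold` for that
#' interaction) is `edgetic`, with the disrupted interactions recorded; all
#' other mutations are non-edgetic and are split on folding stability —
#' folding delta-delta-G at or above `folding_threshold` is `quasi-null`,
#' below it `quasi-wildtype`. The binding test precedes the folding test, so
#' an interface-disrupting mutation is edgetic even if it also destabilises
#' the fold. Burial (`buried` when RSA is at or below `rsa_threshold`,
#' `exposed` above) is recorded for non-edgetic calls but does not enter the
#' label. Non-edgetic mutations with no folding energy are left unlabelled
#' and flagged.
#'
#' @param mutations Tibble with `id`, `location`, `folding_ddg`, `rsa` (and
#'   any carry-through columns).
#' @param binding Tibble (id, ppi_id, binding_ddg) with one row per
#'   (mutation, covered interaction).
#' @param binding_threshold,folding_threshold,rsa_threshold Decision
#'   thresholds (kcal/mol, kcal/mol, RSA fraction).
#' @return Input tibble plus `burial`, `label`, `disrupted_ppis`
#'   (list-column) and logical `unclassified`.
#' @export
classify_edgotype <- function(mutations, binding,
                              binding_threshold = 0.8,
                              folding_threshold = 2,
                              rsa_threshold = 0.25) {
  disrupted <- binding |>
    filter(.data$binding_ddg > binding_threshold) |>
    group_by(.data$id) |>
    summarise(disrupted_ppis = list(sort(unique(.data$ppi_id))))

  out <- mutations |>
    left_join(disrupted, by = "id") |>
    mutate(
      disrupted_ppis = purrr::map(.data$disrupted_ppis,
                                  function(x) x %||% character(0)),
      edgetic = .data$location == "IR" &
        purrr::map_int(.data$disrupted_ppis, length) > 0,
      unclassified = !.data$edgetic & is.na(.data$folding_ddg),
      label = case_when(
        edgetic ~ "edgetic",
        unclassified ~ NA_character_,
        folding_ddg >= folding_threshold ~ "quasi-null",
        TRUE ~ "quasi-wildtype"
      ),
      burial = case_when(
        edgetic ~ NA_character_,
        is.na(rsa) ~ NA_character_,
        rsa <= rsa_threshold ~ "buried",
        TRUE ~ "exposed"
      )
    ) |>
    select(-"edgetic")
  if (any(out$unclassified)) {
    warn(sprintf("%d mutation(s) lacked a folding energy and were left unclassified",
                 sum(out$unclassified)))
  }
  out
}

#' Quasi-null flags in structural-proteome mode
#'
#' In a structural proteome the edgetic branch is unavailable (no
#' interactions), so a missense mutation is flagged quasi-null under one of
#' three definitions: `"ddg_rsa"` (buried, RSA at or below the threshold,
#' and folding delta-delta-G at or above the threshold), `"ddg_only"`
#' (folding threshold alone), or `"rsa_only"` (burial alone).
#'
#' @param mutations Tibble with `folding_ddg` and `rsa`.
#' @param definition `"ddg_rsa"`, `"ddg_only"`, or `"rsa_only"`.
#' @param folding_threshold,rsa_threshold Thresholds.
#' @return Input tibble plus logical column `quasi_null`.
#' @export
classify_superset_quasi_null <- function(mutations,
                                         definition = c("ddg_rsa", "ddg_only",
                                                        "rsa_only"),
                                         folding_threshold = 2,
                                         rsa_threshold = 0.25) {
  definition <- match.arg(definition)
  mutations |>
    mutate(quasi_null = switch(
      definition,
      ddg_rsa = .data$rsa <= rsa_threshold &
        .data$folding_ddg >= folding_threshold,
      ddg_only = .data$folding_ddg >= folding_threshold,
      rsa_only = .data$rsa <= rsa_threshold
    ))
}
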