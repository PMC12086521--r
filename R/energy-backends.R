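default_energy_params <- c(alpha = 1.2, beta = 0.5, gamma = 1.0, noise = 0.3)

# deterministic per-mutation noise keyed on (seed, mutation id)
mutation_noise <- function(ids, seed, scale) {
  if (scale <= 0) return(rep(0, length(ids)))
  vapply(ids, function(id) {
    h <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id)))
    with_substream(seed, paste0("noise", h), rnorm(1, 0, scale))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Deterministic synthetic folding delta-delta-G backend
#'
#' Severity-scaled stand-in for an external force-field call:
#' `ddG = alpha * max(0, -BLOSUM62(ref, alt)) * (1 + beta * (1 - rsa * gamma))
#' + noise(seed, id)`, in kcal/mol, positive = destabilising. Conservative
#' substitutions (positive BLOSUM62 score) contribute zero before noise;
#' identical ref and alt return exactly zero. The noise term is a
#' deterministic function of the seed and mutation id, so identical inputs
#' give identical energies.
#'
#' @param ref,alt Single-letter residue codes (vectorised).
#' @param rsa Relative solvent accessibility of the wildtype residue (`NA`
#'   treated as fully exposed).
#' @param id Mutation ids (drive the deterministic noise).
#' @param seed Integer seed.
#' @param params Named vector `c(alpha, beta, gamma, noise)`.
#' @return Numeric vector of folding delta-delta-G values (kcal/mol).
#' @export
synthetic_folding_ddg <- function(ref, alt, rsa, id, seed = 1L,
                                  params = default_energy_params) {
  p <- default_energy_params
  p[names(params)] <- params
  rsa <- ifelse(is.na(rsa), 1, rsa)
  sev <- pmax(0, -blosum62(ref, alt))
  ddg <- p[["alpha"]] * sev * (1 + p[["beta"]] * (1 - rsa * p[["gamma"]])) +
    mutation_noise(id, seed, p[["noise"]])
  ifelse(ref == alt, 0, ddg)
}

#' Deterministic synthetic binding delta-delta-G backend
#'
#' Severity-scaled stand-in for an interface-energy call:
#' `ddG = alpha * max(0, -BLOSUM62(ref, alt)) + noise(seed, id:ppi)`.
#' Only valid for mutations at an interfacial residue of the given
#' interaction; calling it for a non-interfacial mutation signals a misuse
#' error. Identical ref and alt return exactly zero.
#'
#' @param ref,alt Single-letter residue codes (vectorised).
#' @param id Mutation ids.
#' @param ppi_id Interaction ids (paired with `id`).
#' @param interfacial Logical; is the mutation at an interfacial residue of
#'   `ppi_id`?
#' @param seed Integer seed.
#' @param params Named vector `c(alpha, noise)` (other entries ignored).
#' @return Numeric vector of binding delta-delta-G values (kcal/mol).
#' @export
synthetic_binding_ddg <- function(ref, alt, id, ppi_id, interfacial = TRUE,
                                  seed = 1L,
                                  params = default_energy_params) {
  if (!all(interfacial)) {
    abort("binding delta-delta-G requested for a non-interfacial mutation",
          class = "edgotyper_backend_misuse")
  }
  p <- default_energy_params
  p[names(params)] <- params
  sev <- pmax(0, -blosum62(ref, alt))
  ddg <- p[["alpha"]] * sev +
    mutation_noise(paste0(id, ":", ppi_id), seed, p[["noise"]])
  ifelse(ref == alt, 0, ddg)
}

#' Assemble energy profiles for covered missense mutations
#'
#' Backend-agnostic front end producing, per mutation, the folding
#' delta-delta-G and wildtype-residue RSA, plus one binding delta-delta-G
#' per interaction whose interface the mutation touches. Two built-in
#' backends: `"synthetic"` (the deterministic severity formulas above, RSA
#' computed on the covering model by Shrake-Rupley) and `"truth"` (the
#' generator's recorded draws, for oracle tests). External tool output can
#' be merged instead via [read_energy_table()].
#'
#' @param covered Covered mapped-mutation tibble
#'   (see [filter_structural_coverage()]); missense rows are profiled.
#' @param si Structural interactome the mutations were mapped onto.
#' @param atoms Atom tibble for the template structures (required by the
#'   synthetic backend for RSA).
#' @param backend `"synthetic"` or `"truth"`.
#' @param truth,binding_truth Generator ground-truth tibbles (truth backend).
#' @param seed Integer seed for the deterministic noise.
#' @param params Synthetic-backend parameters.
#' @return List of class `energy_profiles`: `folding` (id, folding_ddg, rsa,
#'   backend) and `binding` (id, ppi_id, binding_ddg).
#' @export
compute_energy_profiles <- function(covered, si, atoms = NULL,
                                    backend = c("synthetic", "truth"),
                                    truth = NULL, binding_truth = NULL,
                                    seed = 1L,
                                    params = default_energy_params) {
  backend <- match.arg(backend)
  miss <- covered[covered$class == "missense", , drop = FALSE]

  touched <- miss |>
    select("id", accession = "canonical_acc", position = "canonical_pos") |>
    inner_join(si$interfaces, by = c("accession", "position"),
               relationship = "many-to-many") |>
    select("id", "ppi_id")

  if (backend == "truth") {
    if (is.null(truth) || is.null(binding_truth)) {
      abort("truth backend requires the generator's ground-truth tables",
            class = "edgotyper_backend_misuse")
    }
    folding <- miss |>
      select("id") |>
      left_join(truth |> select("id", folding_ddg = "true_folding_ddg"),
                by = "id") |>
      mutate(rsa = NA_real_, backend = "truth")
    binding <- touched |>
      inner_join(binding_truth |>
                   rename(binding_ddg = "true_binding_ddg"),
                 by = c("id", "ppi_id"))
    return(structure(list(folding = folding, binding = binding),
                     class = "energy_profiles"))
  }

  if (is.null(atoms)) {
    abort("synthetic backend requires template atoms for RSA",
          class = "edgotyper_backend_misuse")
  }
  # wildtype RSA on the first covering model of each mutation
  first_model <- si$models |>
    distinct(.data$accession, .data$position, .keep_all = TRUE)
  miss_rsa <- miss |>
    left_join(first_model,
              by = c(canonical_acc = "accession", canonical_pos = "position"))
  rsa_tabs <- purrr::map(
    split(atoms, atoms$structure_id)[unique(miss_rsa$structure_id)],
    compute_rsa)
  rsa_of <- function(sid, ch, rn) {
    if (is.na(sid)) return(NA_real_)
    tab <- rsa_tabs[[sid]]
    v <- tab$rsa[tab$chain == ch & tab$resno == rn]
    if (length(v) == 0) NA_real_ else v[[1]]
  }
  rsa <- purrr::pmap_dbl(
    list(miss_rsa$structure_id, miss_rsa$chain, miss_rsa$resno), rsa_of)

  folding <- tibble(
    id = miss$id,
    folding_ddg = synthetic_folding_ddg(miss$ref, miss$alt, rsa, miss$id,
                                        seed, params),
    rsa = rsa,
    backend = "synthetic"
  )
  key <- setNames(seq_len(nrow(miss)), miss$id)
  binding <- touched |>
    mutate(binding_ddg = synthetic_binding_ddg(
      miss$ref[key[.data$id]], miss$alt[key[.data$id]],
      .data$id, .data$ppi_id, interfacial = TRUE, seed = seed,
      params = params))
  structure(list(folding = folding, binding = binding),
            class = "energy_profiles")
}
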