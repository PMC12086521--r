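#' Detect interfacial residues of every synthetic dimer
#'
#' Runs the 5 angstrom all-atom interface detector on each dimer and returns
#' the interfacial residues in canonical protein coordinates (synthetic chain
#' numbering equals canonical numbering).
#'
#' @param ppis Tibble from [generate_ppis()].
#' @param dimers A [generate_dimer_structures()] result.
#' @param cutoff Distance cutoff in angstroms.
#' @return Tibble (ppi_id, accession, position).
#' @export
detect_synthetic_interfaces <- function(ppis, dimers, cutoff = 5) {
  purrr::pmap(ppis, function(ppi_id, acc_a, acc_b, structure_id) {
    at <- dimers$atoms[dimers$atoms$structure_id == structure_id, ]
    ir <- compute_interfacial_residues(at[at$chain == "A", ],
                                       at[at$chain == "B", ],
                                       cutoff = cutoff)
    bind_rows(
      tibble(ppi_id = ppi_id, accession = acc_a, position = ir$a),
      tibble(ppi_id = ppi_id, accession = acc_b, position = ir$b)
    )
  }) |> purrr::list_rbind()
}

#' Generate case/control mutation catalogs with ground truth
#'
#' Draws the disease (case) and non-pathogenic (control) catalogs over the
#' proteins participating in the synthetic interactome. Missense mutations
#' are placed on interfacial residues with the configured per-cohort
#' probability and receive log-normal folding (and, at interfaces, binding)
#' delta-delta-G draws; nonsense records are drawn at the configured cohort
#' fraction; control records carry power-law allele frequencies. Positions
#' are reported in variant-source (perturbed-sequence) coordinates, as a real
#' catalog would, and the ground-truth table keeps the canonical coordinates,
#' the energy draws, and the edgotype label implied by the default thresholds
#' (binding > 0.8 kcal/mol disrupts, else folding >= 2 kcal/mol is
#' quasi-null).
#'
#' @param config A [synthetic_config()].
#' @param proteome A [generate_proteome()] result.
#' @param ppis Tibble from [generate_ppis()].
#' @param interfaces Tibble from [detect_synthetic_interfaces()].
#' @return A list of class `synthetic_catalog` with
#'   - `catalog`: tibble (id, source_acc, position, ref, alt, class, cohort,
#'     af),
#'   - `truth`: tibble (id, cohort, class, canonical_acc, canonical_pos,
#'     source_pos, location, true_folding_ddg, true_label),
#'   - `binding`: tibble (id, ppi_id, true_binding_ddg), one row per
#'     interface placement and covering interaction.
#' @export
generate_mutation_catalog <- function(config, proteome, ppis, interfaces) {
  stopifnot(inherits(config, "synthetic_config"))
  with_substream(config$seed, "mutations", {
    si_proteins <- sort(unique(c(ppis$acc_a, ppis$acc_b)))
    canon <- proteome$canonical[proteome$canonical$accession %in% si_proteins, ]

    # per protein: canonical positions that survived the source perturbation,
    # split into interfacial and non-interfacial sets
    off <- proteome$offsets |>
      filter(!is.na(.data$canonical_pos)) |>
      left_join(proteome$source |> select("source_acc", "canonical_acc"),
                by = "source_acc")
    placements <- purrr::map(canon$accession, function(a) {
      valid <- off$canonical_pos[off$canonical_acc == a]
      iface <- sort(unique(interfaces$position[interfaces$accession == a]))
      list(ir = intersect(iface, valid),
           nir = setdiff(valid, iface),
           all = sort(valid))
    })
    names(placements) <- canon$accession

    one_cohort <- function(cohort, n, nonsense_frac, p_interface, fold_params) {
      acc <- resample(canon$accession, n, replace = TRUE)
      is_nonsense <- runif(n) < nonsense_frac
      want_ir <- !is_nonsense & runif(n) < p_interface
      canonical_pos <- integer(n)
      location <- ifelse(is_nonsense, NA_character_,
                         ifelse(want_ir, "IR", "NIR"))
      for (i in seq_len(n)) {
        p <- placements[[acc[i]]]
        pool <- if (is_nonsense[i]) p$all else if (want_ir[i]) p$ir else p$nir
        if (length(pool) == 0) {       # no interfacial (or no buried) site:
          pool <- p$all                # fall back to any modeled position
          location[i] <- if (is_nonsense[i]) NA_character_ else "NIR"
        }
        canonical_pos[i] <- pool[sample.int(length(pool), 1)]
      }
      tibble(cohort = cohort, canonical_acc = acc, canonical_pos = canonical_pos,
             class = ifelse(is_nonsense, "nonsense", "missense"),
             location = location,
             true_folding_ddg = ifelse(is_nonsense, NA_real_,
                                       sample_ddg(n, fold_params)))
    }

    draws <- bind_rows(
      one_cohort("case", config$n_case_mut, config$nonsense_frac_case,
                 config$p_interface_case, config$ddg_fold_params_case),
      one_cohort("control", config$n_control_mut, config$nonsense_frac_control,
                 config$p_interface_control, config$ddg_fold_params_control)
    )
    draws$id <- sprintf("MUT%06d", seq_len(nrow(draws)))

    # canonical -> source coordinates and reference residues
    seqs <- setNames(proteome$canonical$sequence, proteome$canonical$accession)
    draws <- draws |>
      left_join(off |> select("canonical_acc", "canonical_pos",
                              "source_acc", "source_pos"),
                by = c("canonical_acc", "canonical_pos")) |>
      mutate(ref = substr(seqs[.data$canonical_acc],
                          .data$canonical_pos, .data$canonical_pos))
    alt_missense <- vapply(draws$ref, function(r)
      sample(setdiff(AA20, r), 1), character(1))
    draws$alt <- ifelse(draws$class == "nonsense", "*", alt_missense)
    draws$af <- ifelse(draws$cohort == "control",
                       sample_allele_frequency(nrow(draws),
                                               config$af_exponent,
                                               config$af_range),
                       NA_real_)

    # binding draws for interface placements, one per covering interaction
    binding <- draws |>
      filter(.data$location == "IR") |>
      select("id", accession = "canonical_acc", position = "canonical_pos") |>
      inner_join(interfaces, by = c("accession", "position"),
                 relationship = "many-to-many") |>
      select("id", "ppi_id")
    binding$true_binding_ddg <- sample_ddg(nrow(binding),
                                           config$ddg_bind_params)

    thr <- edgotyper_defaults
    edgetic_ids <- binding |>
      group_by(.data$id) |>
      summarise(edgetic = any(.data$true_binding_ddg > thr$binding_threshold))
    draws <- draws |>
      left_join(edgetic_ids, by = "id") |>
      mutate(
        true_label = case_when(
          class == "nonsense" ~ "nonsense",
          !is.na(edgetic) & edgetic ~ "edgetic",
          true_folding_ddg >= thr$folding_threshold ~ "quasi-null",
          TRUE ~ "quasi-wildtype"
        )
      )

    catalog <- draws |>
      select("id", "source_acc", position = "source_pos",
             "ref", "alt", "class", "cohort", "af")
    truth <- draws |>
      select("id", "cohort", "class", "canonical_acc", "canonical_pos",
             "source_pos", "location", "true_folding_ddg", "true_label")
    structure(list(catalog = catalog, truth = truth, binding = binding),
              class = "synthetic_catalog")
  })
}

#' Generate every input of the pipeline in one call
#'
#' Convenience wrapper running [generate_proteome()], [generate_ppis()],
#' [generate_dimer_structures()], [detect_synthetic_interfaces()], and
#' [generate_mutation_catalog()] under the single config seed.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_study` with elements `config`,
#'   `proteome`, `ppis`, `alignments`, `dimers`, `interfaces`, `catalog`,
#'   `truth`, `binding`.
#' @export
#' @examples
#' study <- synthesize_study(synthetic_config(n_proteins = 8, n_ppis = 5,
#'                                            n_case_mut = 30,
#'                                            n_control_mut = 60, seed = 2))
#' study$catalog
synthesize_study <- function(config) {
  proteome <- generate_proteome(config)
  ppis <- generate_ppis(config, proteome)
  dimers <- generate_dimer_structures(ppis, proteome,
                                      interface_size = config$interface_size,
                                      separation = "contact",
                                      seed = config$seed)
  interfaces <- detect_synthetic_interfaces(ppis, dimers)
  cat_ <- generate_mutation_catalog(config, proteome, ppis, interfaces)
  structure(
    list(config = config, proteome = proteome, ppis = ppis,
         alignments = generate_alignments(ppis, proteome),
         dimers = dimers, interfaces = interfaces,
         catalog = cat_$catalog, truth = cat_$truth, binding = cat_$binding),
    class = "synthetic_study"
  )
}

#' Closed-form fold-difference profile of the generator's severity model
#'
#' For the configured case and control folding delta-delta-G log-normals,
#' returns the exact fold difference `P_case(X >= t) / P_control(X >= t)`
#' over a threshold grid together with the ordinary-least-squares line
#' through the profile. This is the "programmed" profile that a sweep over a
#' sampled catalog estimates.
#'
#' @param params_case,params_control Named vectors `c(meanlog, sdlog, shift)`.
#' @param thresholds Threshold grid (kcal/mol).
#' @return A list with `profile` (tibble threshold, fd), `slope`,
#'   `intercept`.
#' @export
theoretical_fd_profile <- function(params_case, params_control,
                                   thresholds = 1:45) {
  fd <- ddg_tail_prob(thresholds, params_case) /
    ddg_tail_prob(thresholds, params_control)
  fit <- lm(fd ~ thresholds)
  list(profile = tibble(threshold = thresholds, fd = fd),
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]))
}
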