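#' Run the full synthetic-study pipeline
#'
#' End-to-end composition of the package's stages on generated data:
#' synthesize inputs, build the structural interactome from the edge list,
#' alignments and dimer coordinates, re-anchor the mutation catalog on the
#' canonical proteome by flank matching, apply the structural-coverage
#' filter, attach energies from the chosen backend, classify edgotypes, and
#' compute the node-removal fold-difference statistics. Every stage draws
#' its randomness from a named substream of the single config seed, so a
#' given config yields bit-identical results.
#'
#' @param config A [synthetic_config()].
#' @param backend Energy backend: `"truth"` uses the generator's recorded
#'   draws (the study's programmed energies); `"synthetic"` recomputes
#'   energies with the deterministic severity formulas and model-based RSA.
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as re-ingestable text files (FASTA, PDB, alignment and mutation TSVs,
#'   interactome manifest, classified calls, summary).
#' @return A list of class `edgotyper_run`: `study`, `si`, `mapped`,
#'   `covered`, `energies`, `calls`, `fold_differences`, `af_profile`,
#'   `blosum_means`, `summary` (per-stage record counts).
#' @export
#' @examples
#' run <- run_pipeline(synthetic_config(n_proteins = 10, n_ppis = 6,
#'                                      n_case_mut = 50, n_control_mut = 100,
#'                                      seed = 3))
#' run$fold_differences
run_pipeline <- function(config = synthetic_config(),
                         backend = c("truth", "synthetic"),
                         out_dir = NULL) {
  backend <- match.arg(backend)
  study <- synthesize_study(config)

  si <- build_structural_interactome(
    edges = study$ppis |> select("ppi_id", "acc_a", "acc_b"),
    proteins = study$proteome$canonical,
    alignments = study$alignments,
    atoms = study$dimers$atoms,
    structures = study$dimers$structures
  )

  mapped <- map_mutations(study$catalog, study$proteome$source,
                          study$proteome$canonical)
  covered <- filter_structural_coverage(mapped, si) |>
    classify_location(si)

  energies <- compute_energy_profiles(
    covered, si, atoms = study$dimers$atoms, backend = backend,
    truth = study$truth, binding_truth = study$binding, seed = config$seed)

  miss_calls <- covered |>
    filter(.data$class == "missense") |>
    left_join(energies$folding |> select(-"backend"), by = "id") |>
    classify_edgotype(energies$binding)
  calls <- bind_rows(
    miss_calls,
    covered |>
      filter(.data$class == "nonsense") |>
      mutate(location = NA_character_, label = NA_character_,
             burial = NA_character_, unclassified = FALSE,
             disrupted_ppis = list(character(0)))
  )

  fd <- node_removal_fold_differences(calls)
  afp <- af_fraction_profile(calls[calls$cohort == "control", ])
  blosum <- mean_blosum_by_edgotype(calls[calls$class == "missense", ])

  summary <- tibble(
    stage = c("catalog", "mapped", "covered", "classified_missense",
              "structural_ppis"),
    n = c(nrow(study$catalog), nrow(mapped), nrow(covered),
          sum(!is.na(calls$label)), nrow(si$ppis))
  )

  run <- structure(list(
    study = study, si = si, mapped = mapped, covered = covered,
    energies = energies, calls = calls,
    fold_differences = fd, af_profile = afp, blosum_means = blosum,
    summary = summary, backend = backend
  ), class = "edgotyper_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.edgotyper_run <- function(x, ...) {
  cat("edgotyper pipeline run (", x$backend, " backend)\n", sep = "")
  print(x$summary)
  cat("\nFold differences:\n")
  print(x$fold_differences |>
          select("type", "f_case", "f_control", "fd", "se"))
  invisible(x)
}

# write every stage output as re-ingestable text
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(run$study$proteome$canonical, file.path(out_dir, "canonical.fasta"))
  write_fasta(run$study$proteome$source |>
                transmute(accession = .data$source_acc,
                          sequence = .data$sequence),
              file.path(out_dir, "source.fasta"))
  write_blast_tabular(run$study$alignments, file.path(out_dir, "alignments.tsv"))
  write_structure_pdb(run$study$dimers$atoms, file.path(out_dir, "structures"))
  write_mutation_tsv(run$study$catalog, file.path(out_dir, "mutations.tsv"))
  readr::write_tsv(run$study$truth, file.path(out_dir, "ground_truth.tsv"))
  write_si_manifest(run$si, file.path(out_dir, "si_manifest.tsv"))
  readr::write_tsv(run$calls |>
                     mutate(disrupted_ppis = purrr::map_chr(
                       .data$disrupted_ppis, paste, collapse = ",")),
                   file.path(out_dir, "edgotype_calls.tsv"))
  readr::write_tsv(run$fold_differences, file.path(out_dir, "fold_differences.tsv"))
  readr::write_tsv(run$summary, file.path(out_dir, "run_summary.tsv"))
  invisible(out_dir)
}
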