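#' Map gene ids to canonical protein accessions
#'
#' Resolves each gene id through an id-mapping table to the accession with
#' the longest canonical sequence (ties broken by lexicographic accession for
#' determinism). Genes mapping to no canonical accession are dropped with a
#' warning.
#'
#' @param genes Character vector of gene ids.
#' @param id_map Tibble with columns `gene` and `accession`.
#' @param proteins Canonical protein tibble with `accession` and `sequence`.
#' @return Tibble (gene, accession) with one row per resolvable gene.
#' @export
map_gene_to_protein <- function(genes, id_map, proteins) {
  lens <- setNames(nchar(proteins$sequence), proteins$accession)
  mapped <- tibble(gene = genes) |>
    left_join(id_map, by = "gene", relationship = "many-to-many") |>
    filter(.data$accession %in% names(lens)) |>
    mutate(len = lens[.data$accession]) |>
    group_by(.data$gene) |>
    arrange(desc(.data$len), .data$accession, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    select("gene", "accession")
  dropped <- setdiff(genes, mapped$gene)
  if (length(dropped) > 0) {
    warn(sprintf("%d gene(s) had no canonical mapping and were dropped",
                 length(dropped)))
  }
  mapped
}

#' Filter a raw edge list into a reference interactome
#'
#' Applies the reference-map filters: for the literature-curated dialect
#' (`"intact"`), only direct interactions, physical associations, and
#' associations with at least `min_evidence` reports are kept; for the
#' screening dialect (`"hi_union"`) edges are taken as-is. Both dialects then
#' drop self-interactions, restrict endpoints to the canonical protein set,
#' and deduplicate unordered pairs.
#'
#' @param edges Tibble with `acc_a`, `acc_b` and, for the intact dialect,
#'   `interaction_type` and `evidence_count`.
#' @param proteins Canonical protein tibble (`accession`).
#' @param dialect `"hi_union"` or `"intact"`.
#' @param min_evidence Minimum evidence count (intact dialect).
#' @return Tibble (acc_a, acc_b) with acc_a < acc_b.
#' @export
filter_reference_edges <- function(edges, proteins,
                                   dialect = c("hi_union", "intact"),
                                   min_evidence = 2) {
  dialect <- match.arg(dialect)
  physical_types <- c("direct", "physical-association", "association")
  if (dialect == "intact") {
    edges <- edges |>
      filter(.data$interaction_type %in% physical_types,
             .data$evidence_count >= min_evidence)
  }
  edges |>
    filter(.data$acc_a != .data$acc_b,
           .data$acc_a %in% proteins$accession,
           .data$acc_b %in% proteins$accession) |>
    mutate(a = pmin(.data$acc_a, .data$acc_b),
           b = pmax(.data$acc_a, .data$acc_b)) |>
    distinct(.data$a, .data$b) |>
    transmute(acc_a = .data$a, acc_b = .data$b)
}

#' Keep the best alignment per (query, chain) pair
#'
#' Drops alignments with E-value at or above the cutoff and, where a query
#' aligns to the same chain more than once, keeps the smallest-E-value hit
#' (first in input order on ties).
#'
#' @param hits Alignment tibble (see [read_blast_tabular()]).
#' @param max_evalue E-value cutoff (alignments must be strictly below).
#' @return Filtered alignment tibble.
#' @export
filter_alignments <- function(hits, max_evalue = 1e-5) {
  hits |>
    filter(.data$evalue < max_evalue) |>
    mutate(.row = row_number()) |>
    group_by(.data$qacc, .data$structure_id, .data$chain) |>
    arrange(.data$evalue, .data$.row, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    arrange(.data$.row) |>
    select(-".row")
}

#' Aligned-position map of one alignment
#'
#' Walks the aligned query/subject strings and returns the pairs of 1-based
#' positions aligned without a gap on either side.
#'
#' @param qseq,sseq Aligned sequence strings (`-` for gaps).
#' @param qstart,sstart 1-based start positions of the alignment.
#' @return Tibble (qpos, spos), strictly increasing on both sides.
#' @export
alignment_position_map <- function(qseq, sseq, qstart = 1L, sstart = 1L) {
  qc <- seq_chars(qseq)
  sc <- seq_chars(sseq)
  stopifnot(length(qc) == length(sc))
  qgap <- qc == "-"
  sgap <- sc == "-"
  qpos <- qstart - 1L + cumsum(!qgap)
  spos <- sstart - 1L + cumsum(!sgap)
  keep <- !qgap & !sgap
  tibble(qpos = as.integer(qpos[keep]), spos = as.integer(spos[keep]))
}

#' Interfacial residues of a chain pair
#'
#' A residue is interfacial when any of its atoms lies within `cutoff`
#' angstroms of any atom of the partner chain; the criterion is applied
#' symmetrically to both chains. All atoms present in the input are used.
#'
#' @param atoms_a,atoms_b Atom tibbles (columns resno, x, y, z) of the two
#'   chains.
#' @param cutoff Distance cutoff in angstroms (default 5).
#' @return List with integer vectors `a` and `b` of interfacial residue
#'   numbers (sorted, unique); both empty when either chain has no atoms.
#' @export
compute_interfacial_residues <- function(atoms_a, atoms_b, cutoff = 5) {
  if (nrow(atoms_a) == 0 || nrow(atoms_b) == 0) {
    return(list(a = integer(0), b = integer(0)))
  }
  ma <- as.matrix(atoms_a[, c("x", "y", "z")])
  mb <- as.matrix(atoms_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ma^2), rowSums(mb^2), "+") - 2 * tcrossprod(ma, mb)
  close <- d2 <= cutoff^2 + 1e-9
  list(a = sort(unique(atoms_a$resno[rowSums(close) > 0])),
       b = sort(unique(atoms_b$resno[colSums(close) > 0])))
}

#' Select one template chain pair for an interaction
#'
#' Applies the template-selection cascade: structures must have resolution
#' at or below `max_resolution` and both sides' alignment bitscores at or
#' above `min_bitscore`; survivors are ranked by summed bitscore
#' (descending), then total interfacial-residue count (descending), with a
#' deterministic lexicographic tie-break on the chain key. Structures with
#' no resolution record are excluded unless `keep_missing_resolution`.
#'
#' @param candidates Tibble with columns structure_id, chain_a, chain_b,
#'   resolution, bitscore_a, bitscore_b, n_iface.
#' @param max_resolution,min_bitscore Filter thresholds.
#' @param keep_missing_resolution Keep structures with `NA` resolution?
#' @return The selected candidate row (tibble with 1 row), or a 0-row tibble
#'   when no candidate survives.
#' @export
select_template <- function(candidates,
                            max_resolution = 3.5,
                            min_bitscore = 50,
                            keep_missing_resolution = FALSE) {
  ok <- candidates |>
    filter(if (keep_missing_resolution)
             is.na(.data$resolution) | .data$resolution <= max_resolution
           else !is.na(.data$resolution) & .data$resolution <= max_resolution,
           .data$bitscore_a >= min_bitscore,
           .data$bitscore_b >= min_bitscore)
  ok |>
    arrange(desc(.data$bitscore_a + .data$bitscore_b),
            desc(.data$n_iface),
            .data$structure_id, .data$chain_a, .data$chain_b) |>
    slice_head(n = 1)
}

#' Thread a protein onto a template chain
#'
#' Alignment-threading stand-in for homology-model building: protein
#' positions aligned to coordinate-bearing template residues inherit those
#' residues; gap-opposed or unresolved positions are unmodeled. The model
#' length is the number of modeled positions.
#'
#' @param position_map Tibble (qpos, spos) from [alignment_position_map()].
#' @param chain_resnos Residue numbers with coordinates in the template
#'   chain.
#' @return Tibble (position, resno) of modeled protein positions and their
#'   template residues.
#' @export
thread_model <- function(position_map, chain_resnos) {
  keep <- position_map$spos %in% chain_resnos
  tibble(position = position_map$qpos[keep],
         resno = position_map$spos[keep])
}

#' Build a structural interactome
#'
#' For each reference edge, enumerates candidate chain pairs from the two
#' proteins' filtered alignments (same structure only), annotates each
#' candidate with its interfacial residues (5 angstrom all-atom criterion)
#' and requires at least one interfacial residue and at least
#' `min_iface_aligned` of each side's interfacial residues to be covered by
#' the alignment, selects one template per edge with [select_template()],
#' and threads both proteins onto it. Edges with no surviving candidate are
#' dropped.
#'
#' Chain residue numbering is assumed to match the aligned (SEQRES) sequence
#' numbering, as holds for the synthetic generator's output and for
#' renumbered template files.
#'
#' @param edges Tibble (acc_a, acc_b) and optionally ppi_id.
#' @param proteins Canonical protein tibble (`accession`, `sequence`).
#' @param alignments Alignment tibble (see [read_blast_tabular()]).
#' @param atoms Atom tibble (see [read_structure_atoms()]).
#' @param structures Tibble (structure_id, resolution).
#' @param cutoff Interface distance cutoff, angstroms.
#' @param max_evalue,max_resolution,min_bitscore,keep_missing_resolution
#'   Filter thresholds (see [filter_alignments()], [select_template()]).
#' @param min_iface_aligned Minimum fraction of a side's interfacial
#'   residues that must be aligned to the protein.
#' @return A list of class `structural_interactome` with
#'   - `ppis`: manifest tibble (ppi_id, acc_a, acc_b, structure_id, chain_a,
#'     chain_b, n_iface_a, n_iface_b, model_len_a, model_len_b),
#'   - `interfaces`: tibble (ppi_id, accession, position) in protein
#'     coordinates,
#'   - `models`: tibble (ppi_id, accession, position, structure_id, chain,
#'     resno) of modeled positions,
#'   - `proteins`: tibble (accession, length).
#' @export
build_structural_interactome <- function(edges, proteins, alignments, atoms,
                                         structures,
                                         cutoff = 5,
                                         max_evalue = 1e-5,
                                         max_resolution = 3.5,
                                         min_bitscore = 50,
                                         min_iface_aligned = 0.5,
                                         keep_missing_resolution = FALSE) {
  hits <- filter_alignments(alignments, max_evalue)
  if (!"ppi_id" %in% names(edges)) {
    edges$ppi_id <- sprintf("PPI%04d", seq_len(nrow(edges)))
  }
  res_lookup <- setNames(structures$resolution, structures$structure_id)
  atom_split <- split(atoms, paste(atoms$structure_id, atoms$chain, sep = "\r"))
  get_atoms <- function(sid, ch) {
    atom_split[[paste(sid, ch, sep = "\r")]] %||%
      atoms[0, , drop = FALSE]
  }

  per_edge <- purrr::pmap(edges[, c("ppi_id", "acc_a", "acc_b")],
                          function(ppi_id, acc_a, acc_b) {
    ha <- hits[hits$qacc == acc_a, ]
    hb <- hits[hits$qacc == acc_b, ]
    shared <- intersect(ha$structure_id, hb$structure_id)
    if (length(shared) == 0) return(NULL)
    cand <- NULL
    for (sid in shared) {
      for (ia in which(ha$structure_id == sid)) {
        for (ib in which(hb$structure_id == sid)) {
          if (ha$chain[ia] == hb$chain[ib]) next
          at_a <- get_atoms(sid, ha$chain[ia])
          at_b <- get_atoms(sid, hb$chain[ib])
          ir <- compute_interfacial_residues(at_a, at_b, cutoff)
          if (length(ir$a) == 0) next   # criterion: >= 1 interfacial residue
          pm_a <- alignment_position_map(ha$qseq[ia], ha$sseq[ia],
                                         ha$qstart[ia], ha$sstart[ia])
          pm_b <- alignment_position_map(hb$qseq[ib], hb$sseq[ib],
                                         hb$qstart[ib], hb$sstart[ib])
          if (mean(ir$a %in% pm_a$spos) < min_iface_aligned) next
          if (mean(ir$b %in% pm_b$spos) < min_iface_aligned) next
          cand <- bind_rows(cand, tibble(
            ppi_id = ppi_id, acc_a = acc_a, acc_b = acc_b,
            structure_id = sid,
            chain_a = ha$chain[ia], chain_b = hb$chain[ib],
            resolution = unname(res_lookup[sid]),
            bitscore_a = ha$bitscore[ia], bitscore_b = hb$bitscore[ib],
            n_iface = length(ir$a) + length(ir$b),
            data = list(list(ir = ir, pm_a = pm_a, pm_b = pm_b,
                             resno_a = unique(at_a$resno),
                             resno_b = unique(at_b$resno)))
          ))
        }
      }
    }
    if (is.null(cand)) return(NULL)
    sel <- select_template(cand, max_resolution, min_bitscore,
                           keep_missing_resolution)
    if (nrow(sel) == 0) return(NULL)
    d <- sel$data[[1]]
    model_a <- thread_model(d$pm_a, d$resno_a)
    model_b <- thread_model(d$pm_b, d$resno_b)
    iface_a <- d$pm_a$qpos[match(d$ir$a, d$pm_a$spos)]
    iface_b <- d$pm_b$qpos[match(d$ir$b, d$pm_b$spos)]
    list(
      ppi = sel |>
        select(-"data", -"resolution", -"n_iface") |>
        mutate(n_iface_a = length(d$ir$a), n_iface_b = length(d$ir$b),
               model_len_a = nrow(model_a), model_len_b = nrow(model_b)),
      interfaces = bind_rows(
        tibble(ppi_id = ppi_id, accession = acc_a,
               position = sort(iface_a[!is.na(iface_a)])),
        tibble(ppi_id = ppi_id, accession = acc_b,
               position = sort(iface_b[!is.na(iface_b)]))),
      models = bind_rows(
        model_a |> mutate(ppi_id = ppi_id, accession = acc_a,
                          structure_id = sel$structure_id,
                          chain = sel$chain_a),
        model_b |> mutate(ppi_id = ppi_id, accession = acc_b,
                          structure_id = sel$structure_id,
                          chain = sel$chain_b))
    )
  })
  per_edge <- purrr::compact(per_edge)
  empty_models <- tibble(ppi_id = character(0), accession = character(0),
                         position = integer(0), structure_id = character(0),
                         chain = character(0), resno = integer(0))
  structure(list(
    ppis = purrr::list_rbind(purrr::map(per_edge, "ppi")) |>
      (\(x) if (nrow(x) == 0)
        tibble(ppi_id = character(0), acc_a = character(0),
               acc_b = character(0), structure_id = character(0),
               chain_a = character(0), chain_b = character(0),
               bitscore_a = numeric(0), bitscore_b = numeric(0),
               n_iface_a = integer(0), n_iface_b = integer(0),
               model_len_a = integer(0), model_len_b = integer(0))
       else x)(),
    interfaces = purrr::list_rbind(purrr::map(per_edge, "interfaces")) |>
      (\(x) if (nrow(x) == 0)
        tibble(ppi_id = character(0), accession = character(0),
               position = integer(0))
       else x)(),
    models = purrr::list_rbind(purrr::map(per_edge, "models")) |>
      (\(x) if (nrow(x) == 0) empty_models
       else select(x, "ppi_id", "accession", "position", "structure_id",
                   "chain", "resno"))(),
    proteins = proteins |>
      transmute(accession = .data$accession,
                length = nchar(.data$sequence))
  ), class = "structural_interactome")
}

#' Build a structural proteome
#'
#' Selects one template chain per protein: alignments are filtered as for
#' the interactome, candidates must meet the resolution and bitscore
#' thresholds, and the best bitscore wins with ties broken by input order.
#' Each protein is threaded onto its template; proteins with no surviving
#' candidate are absent from the result.
#'
#' @inheritParams build_structural_interactome
#' @return A list of class `structural_proteome` with
#'   - `models`: tibble (accession, position, structure_id, chain, resno),
#'   - `proteins`: tibble (accession, length, model_length, structure_id,
#'     chain) for modeled proteins.
#' @export
build_structural_proteome <- function(proteins, alignments, atoms, structures,
                                      max_evalue = 1e-5,
                                      max_resolution = 3.5,
                                      min_bitscore = 50,
                                      keep_missing_resolution = FALSE) {
  hits <- filter_alignments(alignments, max_evalue)
  res_lookup <- setNames(structures$resolution, structures$structure_id)
  hits <- hits |>
    mutate(resolution = unname(res_lookup[.data$structure_id]),
           .row = row_number()) |>
    filter(if (keep_missing_resolution)
             is.na(.data$resolution) | .data$resolution <= max_resolution
           else !is.na(.data$resolution) & .data$resolution <= max_resolution,
           .data$bitscore >= min_bitscore)

  per_protein <- hits |>
    group_by(.data$qacc) |>
    arrange(desc(.data$bitscore), .data$.row, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup()

  models <- purrr::pmap(
    per_protein[, c("qacc", "structure_id", "chain", "qseq", "sseq",
                    "qstart", "sstart")],
    function(qacc, structure_id, chain, qseq, sseq, qstart, sstart) {
      resnos <- unique(atoms$resno[atoms$structure_id == structure_id &
                                     atoms$chain == chain])
      pm <- alignment_position_map(qseq, sseq, qstart, sstart)
      thread_model(pm, resnos) |>
        mutate(accession = qacc, structure_id = structure_id, chain = chain)
    }) |> purrr::list_rbind()

  lens <- setNames(nchar(proteins$sequence), proteins$accession)
  prot <- models |>
    group_by(.data$accession, .data$structure_id, .data$chain) |>
    summarise(model_length = n(), .groups = "drop") |>
    mutate(length = unname(lens[.data$accession])) |>
    select("accession", "length", "model_length", "structure_id", "chain")
  structure(list(
    models = models |>
      select("accession", "position", "structure_id", "chain", "resno"),
    proteins = prot
  ), class = "structural_proteome")
}
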