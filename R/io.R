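#' Read and write protein FASTA
#'
#' Thin tibble-facing wrappers around Biostrings.
#'
#' @param path File path.
#' @return `read_fasta()` returns a tibble (accession, sequence, length).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  tibble(accession = sub("\\s.*$", "", names(set)),
         sequence = unname(as.character(set)),
         length = Biostrings::width(set))
}

#' @rdname read_fasta
#' @param proteins Tibble with columns `accession` and `sequence`.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(setNames(proteins$sequence,
                                          proteins$accession))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read coordinates from PDB or mmCIF files
#'
#' Parses one or more coordinate files with bio3d and returns a long atom
#' tibble (ATOM records only; waters skipped). The structure id is the file
#' name without extension unless given.
#'
#' @param paths Character vector of `.pdb` / `.cif` paths.
#' @param structure_ids Optional ids, recycled along `paths`.
#' @return Tibble (structure_id, chain, resno, resname, elety, elem, x, y, z).
#' @export
read_structure_atoms <- function(paths, structure_ids = NULL) {
  ids <- structure_ids %||% sub("\\.(pdb|cif|ent)$", "", basename(paths))
  purrr::map2(paths, ids, function(p, id) {
    pdb <- if (grepl("\\.cif$", p)) bio3d::read.cif(p) else bio3d::read.pdb(p)
    at <- pdb$atom
    at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT")), ]
    tibble(structure_id = id, chain = at$chain, resno = at$resno,
           resname = at$resid, elety = at$elety,
           elem = ifelse(is.na(at$elesy) | at$elesy == "",
                         substr(at$elety, 1, 1), at$elesy),
           x = at$x, y = at$y, z = at$z)
  }) |> purrr::list_rbind()
}

#' Write an atom tibble as one PDB file per structure
#'
#' @param atoms Atom tibble as produced by the synthetic generator or
#'   [read_structure_atoms()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_structure_pdb <- function(atoms, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_chr(split(atoms, atoms$structure_id), function(at) {
    path <- file.path(dir, paste0(at$structure_id[1], ".pdb"))
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     resno = at$resno, resid = at$resname,
                     chain = at$chain, elety = at$elety,
                     eleno = seq_len(nrow(at)))
    path
  })
  invisible(unname(paths))
}

#' Read BLAST-style tabular alignments with aligned sequence strings
#'
#' Expects a header-less tab-separated file in the column order
#' qacc, sacc, evalue, bitscore, qstart, qend, sstart, send, qseq, sseq,
#' where `sacc` is `<structure id>_<chain id>` (split on the last
#' underscore).
#'
#' @param path File path.
#' @return Alignment tibble with columns qacc, structure_id, chain, evalue,
#'   bitscore, qstart, qend, sstart, send, qseq, sseq.
#' @export
read_blast_tabular <- function(path) {
  cols <- c("qacc", "sacc", "evalue", "bitscore", "qstart", "qend",
            "sstart", "send", "qseq", "sseq")
  x <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                       col_types = "ccddiiiicc")
  x |>
    mutate(structure_id = sub("_[^_]*$", "", .data$sacc),
           chain = sub("^.*_", "", .data$sacc)) |>
    select("qacc", "structure_id", "chain", "evalue", "bitscore",
           "qstart", "qend", "sstart", "send", "qseq", "sseq")
}

#' @rdname read_blast_tabular
#' @param alignments Alignment tibble (as from [generate_alignments()]).
#' @export
write_blast_tabular <- function(alignments, path) {
  out <- alignments |>
    mutate(sacc = paste(.data$structure_id, .data$chain, sep = "_")) |>
    select("qacc", "sacc", "evalue", "bitscore", "qstart", "qend",
           "sstart", "send", "qseq", "sseq")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read and write the mutation-catalog TSV
#'
#' Catalog dialect: columns id, source_acc, position, ref, alt, class
#' (`missense`/`nonsense`), cohort (`case`/`control`), af (empty when
#' unknown). Premature stops are encoded as `*`.
#'
#' @param path File path.
#' @return Tibble with the catalog columns.
#' @export
read_mutation_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    id = "c", source_acc = "c", position = "i", ref = "c",
                    alt = "c", class = "c", cohort = "c", af = "d"))
}

#' @rdname read_mutation_tsv
#' @param catalog Catalog tibble.
#' @export
write_mutation_tsv <- function(catalog, path) {
  readr::write_tsv(catalog, path)
  invisible(path)
}

#' Write the structural-interactome manifest
#'
#' One row per structurally resolved interaction: the selected template
#' chain pair, per-side interface sizes, and per-side model lengths.
#'
#' @param si A structural interactome (see [build_structural_interactome()]).
#' @param path Output TSV path.
#' @export
write_si_manifest <- function(si, path) {
  readr::write_tsv(si$ppis, path)
  invisible(path)
}
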