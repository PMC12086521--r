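#' Generate a toy proteome with variant-source sequence copies
#'
#' Draws `n_proteins` random canonical sequences over the 20-residue alphabet
#' and derives one variant-source ("RefSeq-like") copy per protein by applying
#' random insertions and deletions at rate `indel_rate`, recording the exact
#' position-offset map between the two coordinate systems. Downstream,
#' mutation catalogs are expressed in variant-source coordinates and must be
#' re-anchored on the canonical sequences by flanking-sequence matching.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_proteome` with
#'   - `canonical`: tibble (accession, sequence, length),
#'   - `source`: tibble (source_acc, canonical_acc, sequence, length),
#'   - `offsets`: tibble (source_acc, source_pos, canonical_pos) where
#'     `canonical_pos` is `NA` for residues inserted into the source copy.
#' @export
#' @examples
#' prot <- generate_proteome(synthetic_config(n_proteins = 4, seed = 7))
#' prot$canonical
generate_proteome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_substream(config$seed, "proteome", {
    lens <- resample(config$length_range[1]:config$length_range[2],
                     config$n_proteins, replace = TRUE)
    acc <- sprintf("SYNP%04d", seq_len(config$n_proteins))
    seqs <- vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
    canonical <- tibble(accession = acc, sequence = seqs, length = lens)

    perturbed <- purrr::map(seqs, perturb_sequence,
                            indel_rate = config$indel_rate,
                            max_indel_len = config$max_indel_len)
    src_acc <- sprintf("R_%s", acc)
    source <- tibble(
      source_acc = src_acc,
      canonical_acc = acc,
      sequence = purrr::map_chr(perturbed, "sequence"),
      length = nchar(purrr::map_chr(perturbed, "sequence"))
    )
    offsets <- purrr::map2(perturbed, src_acc, function(p, a) {
      tibble(source_acc = a,
             source_pos = seq_along(p$map),
             canonical_pos = p$map)
    }) |> purrr::list_rbind()

    structure(list(canonical = canonical, source = source, offsets = offsets),
              class = "synthetic_proteome")
  })
}

# Apply indels to one sequence. At each canonical position an indel event
# starts with probability indel_rate; deletions drop up to max_indel_len
# canonical residues, insertions add up to max_indel_len random residues.
# Returns the perturbed sequence and, per perturbed position, the canonical
# position it copies (NA for insertions).
perturb_sequence <- function(sequence, indel_rate, max_indel_len) {
  chars <- seq_chars(sequence)
  L <- length(chars)
  if (indel_rate <= 0) {
    return(list(sequence = sequence, map = seq_len(L)))
  }
  out <- character(0)
  map <- integer(0)
  i <- 1L
  while (i <= L) {
    if (runif(1) < indel_rate) {
      len <- sample.int(max_indel_len, 1)
      if (runif(1) < 0.5) {           # deletion: skip canonical residues
        i <- i + len
        next
      } else {                        # insertion before position i
        out <- c(out, sample(AA20, len, replace = TRUE))
        map <- c(map, rep(NA_integer_, len))
      }
    }
    out <- c(out, chars[i])
    map <- c(map, i)
    i <- i + 1L
  }
  if (length(out) == 0L) {            # degenerate: keep one residue
    out <- chars[1]; map <- 1L
  }
  list(sequence = paste(out, collapse = ""), map = map)
}

#' Sample a set of binary interactions for the toy proteome
#'
#' Draws `n_ppis` distinct unordered protein pairs; each pair receives one
#' synthetic dimer structure id.
#'
#' @param config A [synthetic_config()].
#' @param proteome A [generate_proteome()] result.
#' @return Tibble (ppi_id, acc_a, acc_b, structure_id).
#' @export
generate_ppis <- function(config, proteome) {
  with_substream(config$seed, "ppis", {
    acc <- proteome$canonical$accession
    pairs <- utils::combn(acc, 2)
    keep <- sample.int(ncol(pairs), config$n_ppis)
    tibble(
      ppi_id = sprintf("PPI%04d", seq_len(config$n_ppis)),
      acc_a = pairs[1, keep],
      acc_b = pairs[2, keep],
      structure_id = sprintf("syn%04d", seq_len(config$n_ppis))
    )
  })
}

#' Emit identity alignments between canonical proteins and dimer chains
#'
#' Produces BLAST-tabular-style alignment records (with aligned sequence
#' strings) that align each interacting protein perfectly onto its chain in
#' the corresponding synthetic dimer, so the assembly stage can run on
#' synthetic data exactly as it would on real search output.
#'
#' @param ppis Tibble from [generate_ppis()].
#' @param proteome A [generate_proteome()] result.
#' @return Tibble with columns qacc, structure_id, chain, evalue, bitscore,
#'   qstart, qend, sstart, send, qseq, sseq.
#' @export
generate_alignments <- function(ppis, proteome) {
  seqs <- setNames(proteome$canonical$sequence, proteome$canonical$accession)
  long <- tidyr::pivot_longer(ppis, c("acc_a", "acc_b"),
                              names_to = "side", values_to = "qacc")
  lens <- unname(nchar(seqs[long$qacc]))
  tibble(
    qacc = long$qacc,
    structure_id = long$structure_id,
    chain = ifelse(long$side == "acc_a", "A", "B"),
    evalue = 1e-50,
    bitscore = 2 * lens,
    qstart = 1L,
    qend = lens,
    sstart = 1L,
    send = lens,
    qseq = unname(seqs[long$qacc]),
    sseq = unname(seqs[long$qacc])
  )
}
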