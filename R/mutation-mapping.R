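#' Extract the flanking-sequence pattern of a mutation site
#'
#' Returns the up-to-10 residues on either side of the site plus the
#' reference residue itself, truncated at the sequence ends, together with
#' the 1-based offset of the site within the pattern.
#'
#' @param sequence Source protein sequence.
#' @param position 1-based mutation position.
#' @param flank Residues to take on each side (default 10).
#' @return List with `pattern` (string) and `site_offset` (integer), or an
#'   error of class `edgotyper_position_error` when `position` is out of
#'   range.
#' @export
#' @examples
#' extract_flank("MKTAYIAKQRQISFVKSHFSRQ", 5)
extract_flank <- function(sequence, position, flank = 10) {
  L <- nchar(sequence)
  if (is.na(position) || position < 1 || position > L) {
    abort(sprintf("position %s out of range for sequence of length %d",
                  position, L),
          class = "edgotyper_position_error")
  }
  lo <- max(1L, position - flank)
  hi <- min(L, position + flank)
  list(pattern = substr(sequence, lo, hi),
       site_offset = as.integer(position - lo + 1L))
}

#' Locate a flanking pattern on a canonical sequence
#'
#' Searches for exact occurrences of the pattern. A unique occurrence yields
#' the canonical site position (which may differ from the source position —
#' discrepancies are attributed to indels between the databases and
#' retained); zero occurrences mean the mutation is unmapped; multiple
#' occurrences are ambiguous and the record is discarded.
#'
#' @param pattern Flank pattern string.
#' @param site_offset Offset of the mutation site within the pattern.
#' @param canonical_sequence Canonical protein sequence.
#' @return List with `status` (`"mapped"`, `"unmapped"`, or `"ambiguous"`)
#'   and `position` (canonical site position, `NA` unless mapped).
#' @export
map_to_canonical <- function(pattern, site_offset, canonical_sequence) {
  m <- gregexpr(pattern, canonical_sequence, fixed = TRUE)[[1]]
  starts <- m[m > 0]
  if (length(starts) == 0) {
    list(status = "unmapped", position = NA_integer_)
  } else if (length(starts) > 1) {
    list(status = "ambiguous", position = NA_integer_)
  } else {
    list(status = "mapped",
         position = as.integer(starts + site_offset - 1L))
  }
}

#' Map a mutation catalog onto canonical proteins
#'
#' Re-anchors every record from source-protein coordinates to canonical
#' coordinates by exact flanking-sequence matching, then deduplicates to one
#' record per unique amino-acid change at each canonical position.
#' Records whose position is invalid, whose flank has no exact canonical
#' match, or whose flank matches more than once are dropped and counted in
#' the attached report.
#'
#' @param catalog Mutation catalog tibble (see [read_mutation_tsv()]).
#' @param source Source-protein tibble (`source_acc`, `canonical_acc`,
#'   `sequence`).
#' @param canonical Canonical protein tibble (`accession`, `sequence`).
#' @param flank Flank width per side (default 10).
#' @return Tibble of mapped records (catalog columns plus `canonical_acc`,
#'   `canonical_pos`), with a `report` attribute counting mapped / unmapped
#'   / ambiguous / invalid-position / dedup-removed records (retrievable via
#'   [mapping_report()]).
#' @export
map_mutations <- function(catalog, source, canonical, flank = 10) {
  src_seq <- setNames(source$sequence, source$source_acc)
  src_canon <- setNames(source$canonical_acc, source$source_acc)
  canon_seq <- setNames(canonical$sequence, canonical$accession)

  status <- character(nrow(catalog))
  pos <- integer(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    sacc <- catalog$source_acc[i]
    if (!sacc %in% names(src_seq) ||
        !src_canon[[sacc]] %in% names(canon_seq)) {
      status[i] <- "no_sequence"; pos[i] <- NA_integer_; next
    }
    fl <- tryCatch(extract_flank(src_seq[[sacc]], catalog$position[i], flank),
                   edgotyper_position_error = function(e) NULL)
    if (is.null(fl)) {
      status[i] <- "invalid_position"; pos[i] <- NA_integer_; next
    }
    hit <- map_to_canonical(fl$pattern, fl$site_offset,
                            canon_seq[[src_canon[[sacc]]]])
    status[i] <- hit$status
    pos[i] <- hit$position
  }

  mapped <- catalog |>
    mutate(canonical_acc = unname(src_canon[.data$source_acc]),
           canonical_pos = pos,
           .status = status) |>
    filter(.data$.status == "mapped")

  # ref-residue consistency is guaranteed by the exact match but asserted
  # here as a guard on caller-supplied sequences
  ref_ok <- substr(canon_seq[mapped$canonical_acc],
                   mapped$canonical_pos, mapped$canonical_pos) == mapped$ref
  if (!all(ref_ok)) {
    abort("mapped reference residues disagree with canonical sequences",
          class = "edgotyper_internal_error")
  }

  deduped <- dedup_mutations(select(mapped, -".status"))
  if (sum(status == "ambiguous") > 0) {
    warn(sprintf("%d mutation(s) had multiple exact flank matches and were discarded",
                 sum(status == "ambiguous")))
  }
  n_before_dedup <- nrow(mapped)
  report <- tibble(
    total = nrow(catalog),
    mapped = nrow(deduped),
    unmapped = sum(status == "unmapped"),
    ambiguous = sum(status == "ambiguous"),
    invalid_position = sum(status %in% c("invalid_position", "no_sequence")),
    dedup_removed = n_before_dedup - nrow(deduped)
  )
  attr(deduped, "report") <- report
  deduped
}

#' @rdname map_mutations
#' @param mapped A [map_mutations()] result.
#' @export
mapping_report <- function(mapped) attr(mapped, "report")

#' Deduplicate mapped mutations
#'
#' Keeps one record per unique amino-acid change — per (canonical accession,
#' canonical position, ref, alt) — retaining the first in stable input
#' order. Idempotent.
#'
#' @param mapped Tibble with columns canonical_acc, canonical_pos, ref, alt.
#' @return Deduplicated tibble.
#' @export
dedup_mutations <- function(mapped) {
  mapped |>
    distinct(.data$canonical_acc, .data$canonical_pos, .data$ref, .data$alt,
             .keep_all = TRUE)
}

#' Filter mapped mutations by structural coverage
#'
#' Missense records are kept when their canonical position is modeled in at
#' least one structural model of their protein. Nonsense records lack a
#' mutant structure: by default they are kept whenever their protein carries
#' at least one model (`nonsense_rule = "protein"`); set
#' `nonsense_rule = "position"` to additionally require the truncation site
#' itself to be modeled.
#'
#' @param mapped Mapped mutation tibble (see [map_mutations()]).
#' @param si A `structural_interactome` or `structural_proteome`.
#' @param nonsense_rule `"protein"` or `"position"`.
#' @return Covered subset with logical column `covered_by_model` (always
#'   `TRUE` in the result) and, for interactome input, a list-column
#'   `covering_ppis` of the interactions whose models cover the position.
#' @export
filter_structural_coverage <- function(mapped, si,
                                       nonsense_rule = c("protein", "position")) {
  nonsense_rule <- match.arg(nonsense_rule)
  models <- si$models
  has_ppi <- "ppi_id" %in% names(models)
  key <- paste(models$accession, models$position)
  modeled_proteins <- unique(models$accession)

  pos_key <- paste(mapped$canonical_acc, mapped$canonical_pos)
  pos_covered <- pos_key %in% key
  keep <- ifelse(mapped$class == "missense",
                 pos_covered,
                 if (nonsense_rule == "position") pos_covered
                 else mapped$canonical_acc %in% modeled_proteins)
  out <- mapped[keep, , drop = FALSE]
  out$covered_by_model <- TRUE
  if (has_ppi) {
    cover <- split(models$ppi_id, paste(models$accession, models$position))
    out$covering_ppis <- purrr::map(
      paste(out$canonical_acc, out$canonical_pos),
      function(k) unique(cover[[k]]) %||% character(0))
  }
  out
}
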