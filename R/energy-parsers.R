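#' Read external energy-tool output tables
#'
#' Parsers for three external dialects, attaching values to
#' (mutation, model) keys:
#' - `"buildmodel"`: whitespace/tab-separated stability table with a header
#'   and at least two columns, a mutation id and the folding delta-delta-G
#'   (mutant minus wildtype, kcal/mol).
#' - `"pssm"`: interface-scan matrix; the first header field names nothing,
#'   the remaining header fields are mutation sites written as
#'   `<ref><position>` (e.g. `A42`); each following row starts with the
#'   substituted residue letter and lists the binding delta-delta-G per
#'   site.
#' - `"dssp"`: classic per-residue secondary-structure output; the residue
#'   number, chain, amino acid and accessibility (`ACC`, square angstroms)
#'   columns are read and RSA is derived by dividing by the residue's
#'   theoretical maximum area.
#'
#' Unparseable data rows are reported in the `problems` attribute (line
#' number and content), never silently dropped; a structurally malformed
#' file signals `edgotyper_parse_error` with the offending line number.
#'
#' @param path File path.
#' @param dialect `"buildmodel"`, `"pssm"`, or `"dssp"`.
#' @return A tibble of energy fragments: `(id, folding_ddg)` for
#'   buildmodel, `(site, ref, position, alt, binding_ddg)` for pssm, and
#'   `(chain, resno, aa, acc, rsa)` for dssp.
#' @export
read_energy_table <- function(path, dialect = c("buildmodel", "pssm", "dssp")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  switch(dialect,
         buildmodel = parse_buildmodel(lines),
         pssm = parse_pssm(lines),
         dssp = parse_dssp(lines))
}

parse_fail <- function(line_no, msg) {
  abort(sprintf("line %d: %s", line_no, msg),
        class = "edgotyper_parse_error")
}

with_problems <- function(tbl, problems) {
  attr(tbl, "problems") <- problems
  tbl
}

parse_buildmodel <- function(lines) {
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0) {
    return(with_problems(tibble(id = character(0), folding_ddg = numeric(0)),
                         tibble(line = integer(0), content = character(0))))
  }
  header <- strsplit(trimws(lines[lines_keep[1]]), "[ \t]+")[[1]]
  if (length(header) < 2) parse_fail(lines_keep[1], "expected >= 2 header fields")
  rows <- lines_keep[-1]
  ids <- character(0); vals <- numeric(0)
  bad <- tibble(line = integer(0), content = character(0))
  for (ln in rows) {
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    v <- suppressWarnings(as.numeric(f[2]))
    if (length(f) < 2 || is.na(v)) {
      bad <- bind_rows(bad, tibble(line = ln, content = lines[ln]))
    } else {
      ids <- c(ids, f[1]); vals <- c(vals, v)
    }
  }
  with_problems(tibble(id = ids, folding_ddg = vals), bad)
}

parse_pssm <- function(lines) {
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0) {
    return(with_problems(
      tibble(site = character(0), ref = character(0),
             position = integer(0), alt = character(0),
             binding_ddg = numeric(0)),
      tibble(line = integer(0), content = character(0))))
  }
  header <- strsplit(trimws(lines[lines_keep[1]]), "[ \t]+")[[1]]
  sites <- header[nzchar(header)]
  if (!all(grepl("^[A-Z][0-9]+$", sites))) {
    parse_fail(lines_keep[1], "header fields must be <ref><position> sites")
  }
  out <- NULL
  bad <- tibble(line = integer(0), content = character(0))
  for (ln in lines_keep[-1]) {
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (length(f) != length(sites) + 1 || !grepl("^[A-Z]$", f[1]) ||
        anyNA(vals)) {
      bad <- bind_rows(bad, tibble(line = ln, content = lines[ln]))
      next
    }
    out <- bind_rows(out, tibble(
      site = sites,
      ref = substr(sites, 1, 1),
      position = as.integer(sub("^[A-Z]", "", sites)),
      alt = f[1],
      binding_ddg = vals))
  }
  with_problems(out %||% tibble(site = character(0), ref = character(0),
                                position = integer(0), alt = character(0),
                                binding_ddg = numeric(0)),
                bad)
}

parse_dssp <- function(lines) {
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) {
    if (all(!nzchar(trimws(lines)))) {
      return(with_problems(tibble(chain = character(0), resno = integer(0),
                                  aa = character(0), acc = numeric(0),
                                  rsa = numeric(0)),
                           tibble(line = integer(0), content = character(0))))
    }
    parse_fail(1L, "no '  #  RESIDUE' header line found")
  }
  rows <- seq(hdr[1] + 1, length(lines))
  recs <- NULL
  bad <- tibble(line = integer(0), content = character(0))
  aa3 <- setNames(names(AA1), AA1)  # one-letter -> three-letter
  for (ln in rows) {
    l <- lines[ln]
    if (!nzchar(trimws(l))) next
    resno <- suppressWarnings(as.integer(substr(l, 6, 10)))
    chain <- trimws(substr(l, 12, 12))
    aa <- trimws(substr(l, 14, 14))
    acc <- suppressWarnings(as.numeric(substr(l, 35, 38)))
    if (is.na(resno) || is.na(acc) || !nzchar(aa)) {
      if (aa == "!") next                      # chain-break marker
      bad <- bind_rows(bad, tibble(line = ln, content = l))
      next
    }
    recs <- bind_rows(recs, tibble(chain = chain, resno = resno, aa = aa,
                                   acc = acc))
  }
  out <- (recs %||% tibble(chain = character(0), resno = integer(0),
                           aa = character(0), acc = numeric(0))) |>
    mutate(rsa = pmin(1, .data$acc / unname(MAX_ASA[aa3[.data$aa]])))
  with_problems(out, bad)
}
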