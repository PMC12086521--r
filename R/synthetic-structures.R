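#' Generate synthetic dimer coordinates with programmed interfaces
#'
#' Builds one two-chain coordinate set per interaction. Each chain is a
#' jittered-lattice C-alpha walk (3.8 angstrom steps) with one pseudo
#' side-chain atom per residue. For `separation = "contact"`, a run of
#' `interface_size` residues of chain B is placed 4.2 angstroms from the
#' matching run of chain A, guaranteeing at least `interface_size` residues
#' per side within the 5 angstrom interface cutoff; for
#' `separation = "apart"` chain B is translated at least 50 angstroms away
#' from chain A, guaranteeing an empty interface. Geometry is deliberately
#' unphysical: only inter-atomic distances matter downstream.
#'
#' @param ppis Tibble from [generate_ppis()].
#' @param proteome A [generate_proteome()] result (chain lengths and residue
#'   names follow the canonical sequences).
#' @param interface_size Programmed contact residues per side.
#' @param separation `"contact"` or `"apart"`.
#' @param seed Integer seed.
#' @return A list of class `synthetic_dimers` with
#'   - `atoms`: tibble (structure_id, chain, resno, resname, elety, elem,
#'     x, y, z),
#'   - `structures`: tibble (structure_id, resolution),
#'   - `contacts`: tibble (ppi_id, structure_id, astart, bstart, size) giving
#'     the programmed contact runs.
#' @export
generate_dimer_structures <- function(ppis, proteome, interface_size = 8,
                                      separation = c("contact", "apart"),
                                      seed = 1L) {
  separation <- match.arg(separation)
  stopifnot(interface_size >= 0)
  seqs <- setNames(proteome$canonical$sequence, proteome$canonical$accession)
  with_substream(seed, "dimers", {
    per_ppi <- purrr::pmap(ppis, function(ppi_id, acc_a, acc_b, structure_id) {
      build_dimer(structure_id, seqs[[acc_a]], seqs[[acc_b]],
                  interface_size, separation)
    })
    atoms <- purrr::list_rbind(purrr::map(per_ppi, "atoms"))
    contacts <- tibble(
      ppi_id = ppis$ppi_id,
      structure_id = ppis$structure_id,
      astart = purrr::map_int(per_ppi, "astart"),
      bstart = purrr::map_int(per_ppi, "bstart"),
      size = as.integer(interface_size)
    )
    structures <- tibble(structure_id = ppis$structure_id, resolution = 2.0)
    structure(list(atoms = atoms, structures = structures, contacts = contacts),
              class = "synthetic_dimers")
  })
}

# C-alpha walk: lattice directions scaled to 3.8 A plus jitter, no
# immediate backtracking.
ca_walk <- function(n, origin = c(0, 0, 0)) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)) * 3.8
  xyz <- matrix(0, n, 3)
  xyz[1, ] <- origin
  prev <- 0L
  for (i in seq_len(n)[-1]) {
    ok <- setdiff(1:6, prev)
    d <- sample(ok, 1)
    prev <- d + ifelse(d %% 2 == 1, 1L, -1L)  # opposite direction index
    xyz[i, ] <- xyz[i - 1, ] + dirs[d, ] + rnorm(3, 0, 0.25)
  }
  xyz
}

chain_atoms <- function(structure_id, chain, sequence, ca) {
  L <- nchar(sequence)
  res <- seq_chars(sequence)
  m <- matrix(rnorm(3 * L, 0, 1), L, 3)
  cb <- ca + 1.5 * m / sqrt(rowSums(m^2))
  tibble(
    structure_id = structure_id,
    chain = chain,
    resno = rep(seq_len(L), each = 2),
    resname = rep(unname(AA3[res]), each = 2),
    elety = rep(c("CA", "CB"), L),
    elem = "C",
    x = as.vector(rbind(ca[, 1], cb[, 1])),
    y = as.vector(rbind(ca[, 2], cb[, 2])),
    z = as.vector(rbind(ca[, 3], cb[, 3]))
  )
}

build_dimer <- function(structure_id, seq_a, seq_b, k, separation) {
  la <- nchar(seq_a); lb <- nchar(seq_b)
  ca_a <- ca_walk(la)
  astart <- if (k > 0) sample.int(la - k + 1, 1) else 1L
  bstart <- if (k > 0) sample.int(lb - k + 1, 1) else 1L

  if (separation == "contact" && k > 0) {
    # chain B run copies chain A's run, displaced 4.2 A along +x (with a
    # touch of jitter kept well inside the 5 A cutoff)
    ca_b <- matrix(NA_real_, lb, 3)
    run_b <- bstart:(bstart + k - 1)
    ca_b[run_b, ] <- ca_a[astart:(astart + k - 1), , drop = FALSE] +
      cbind(4.2 + runif(k, -0.15, 0.15), rnorm(k, 0, 0.1), rnorm(k, 0, 0.1))
    # grow the rest of chain B away from chain A (+x biased walk)
    grow <- function(from, n) {
      out <- matrix(0, n, 3)
      cur <- from
      for (i in seq_len(n)) {
        step <- c(abs(rnorm(1, 2.5, 1)), rnorm(2, 0, 2.5))
        step <- 3.8 * step / sqrt(sum(step^2))
        cur <- cur + step
        out[i, ] <- cur
      }
      out
    }
    if (bstart > 1) {
      ca_b[(bstart - 1):1, ] <- grow(ca_b[bstart, ], bstart - 1)
    }
    if (bstart + k <= lb) {
      n_suf <- lb - (bstart + k) + 1
      ca_b[(bstart + k):lb, ] <- grow(ca_b[bstart + k - 1, ], n_suf)
    }
  } else {
    ca_b <- ca_walk(lb)
    gap <- max(ca_a[, 1]) - min(ca_b[, 1]) + 60
    ca_b[, 1] <- ca_b[, 1] + gap
  }

  atoms <- bind_rows(
    chain_atoms(structure_id, "A", seq_a, ca_a),
    chain_atoms(structure_id, "B", seq_b, ca_b)
  )
  list(atoms = atoms, astart = as.integer(astart), bstart = as.integer(bstart))
}
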