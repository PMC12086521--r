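# Theoretical maximum accessible surface areas (A^2) per residue type,
# Tien et al. (2013)-style theoretical values, used to normalise SASA into
# relative solvent accessibility.
MAX_ASA <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
)

#' Maximum accessible surface area table
#'
#' Theoretical per-residue maximum solvent-accessible surface areas (square
#' angstroms) used as RSA denominators.
#'
#' @return Named numeric vector keyed by 3-letter residue code.
#' @export
max_asa_table <- function() MAX_ASA

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# deterministic quasi-uniform sphere points (golden-spiral construction)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area and RSA per residue
#'
#' Numerical Shrake-Rupley integration: each atom's sphere (van der Waals
#' radius plus a 1.4 angstrom probe) is sampled at `n_points`
#' deterministically placed points, points buried inside any other atom's
#' expanded sphere are discarded, and the per-residue SASA is the summed
#' accessible area of its atoms. RSA divides by the residue type's
#' theoretical maximum and is clipped to [0, 1].
#'
#' @param atoms Atom tibble (columns chain, resno, resname, elem, x, y, z);
#'   all atoms present occlude each other (no hydrogen addition).
#' @param n_points Sphere points per atom (default 120).
#' @param probe Probe radius in angstroms (default 1.4).
#' @return Tibble (chain, resno, resname, sasa, rsa), one row per residue.
#' @export
compute_rsa <- function(atoms, n_points = 120, probe = 1.4) {
  if (nrow(atoms) == 0) {
    return(tibble(chain = character(0), resno = integer(0),
                  resname = character(0), sasa = numeric(0), rsa = numeric(0)))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  elem <- atoms$elem %||% substr(atoms$elety, 1, 1)
  rad <- unname(VDW_RADII[elem])
  rad[is.na(rad)] <- 1.70
  rext <- rad + probe
  pts <- sphere_points(n_points)
  n <- nrow(xyz)

  # neighbour lists from the pairwise-distance prefilter
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  atom_area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rext[i] + rext)^2 & seq_len(n) != i)
    p <- sweep(pts * rext[i], 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dd <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        free <- free & dd > rext[j]^2
      }
      frac <- mean(free)
    } else {
      frac <- 1
    }
    atom_area[i] <- frac * 4 * pi * rext[i]^2
  }

  tibble(chain = atoms$chain, resno = atoms$resno, resname = atoms$resname,
         area = atom_area) |>
    group_by(.data$chain, .data$resno, .data$resname) |>
    summarise(sasa = sum(.data$area), .groups = "drop") |>
    mutate(rsa = pmin(1, .data$sasa /
                        unname(MAX_ASA[.data$resname]) %||% NA_real_)) |>
    arrange(.data$chain, .data$resno)
}

#' RSA of one modeled residue
#'
#' Convenience accessor computing [compute_rsa()] over a structure's atoms
#' and returning the RSA of a single residue. Signals a missing-structure
#' error for unmodeled positions.
#'
#' @param atoms Atom tibble of the structure the residue sits in.
#' @param chain,resno Residue key.
#' @param ... Passed to [compute_rsa()].
#' @return RSA in [0, 1].
#' @export
residue_rsa <- function(atoms, chain, resno, ...) {
  tab <- compute_rsa(atoms, ...)
  row <- tab[tab$chain == chain & tab$resno == resno, ]
  if (nrow(row) == 0) {
    abort(sprintf("residue %s/%s is not present in the structure",
                  chain, resno),
          class = "edgotyper_missing_structure")
  }
  row$rsa[[1]]
}
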