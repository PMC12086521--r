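# Small shared fixtures, all built in code.

tiny_config <- function(seed = 1L, ...) {
  synthetic_config(n_proteins = 10, n_ppis = 6, interface_size = 6,
                   n_case_mut = 60, n_control_mut = 120, seed = seed, ...)
}

tiny_study <- local({
  cache <- list()
  function(seed = 1L, ...) {
    key <- paste(seed, paste(deparse(list(...)), collapse = ""))
    if (is.null(cache[[key]])) {
      cache[[key]] <<- synthesize_study(tiny_config(seed = seed, ...))
    }
    cache[[key]]
  }
})

# independent all-pair brute-force interface oracle (plain loops over
# residue pairs, no shared code with the implementation)
brute_force_interface <- function(atoms_a, atoms_b, cutoff = 5) {
  res_a <- integer(0); res_b <- integer(0)
  for (ra in unique(atoms_a$resno)) {
    aa <- atoms_a[atoms_a$resno == ra, ]
    for (rb in unique(atoms_b$resno)) {
      bb <- atoms_b[atoms_b$resno == rb, ]
      hit <- FALSE
      for (i in seq_len(nrow(aa))) {
        for (j in seq_len(nrow(bb))) {
          d <- sqrt((aa$x[i] - bb$x[j])^2 + (aa$y[i] - bb$y[j])^2 +
                      (aa$z[i] - bb$z[j])^2)
          if (d <= cutoff) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit) { res_a <- c(res_a, ra); res_b <- c(res_b, rb) }
    }
  }
  list(a = sort(unique(res_a)), b = sort(unique(res_b)))
}

# random free-floating atom cloud used for geometry tests
random_chain_atoms <- function(n_res, chain = "A", spread = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    structure_id = "toy", chain = chain,
    resno = rep(seq_len(n_res), each = 2),
    resname = rep(sample(names(edgotyper::max_asa_table()), n_res,
                         replace = TRUE), each = 2),
    elety = rep(c("CA", "CB"), n_res),
    elem = "C",
    x = stats::runif(2 * n_res, 0, spread),
    y = stats::runif(2 * n_res, 0, spread),
    z = stats::runif(2 * n_res, 0, spread)
  )
}
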