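AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA1 <- setNames(names(AA3), AA3)

# Deterministic sub-stream seed derived from the run seed and a stage name.
# Keeps every stage's randomness reproducible from a single integer seed
# while decoupling the streams of different stages. Result stays < 2^31.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 97 + 1) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

# sample() that never falls into the length-1 integer trap
resample <- function(x, ...) x[sample.int(length(x), ...)]

# stable string chopper: "ABC" -> c("A","B","C")
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62
    }
    cache
  }
})

#' BLOSUM62 substitution score
#'
#' Looks up the BLOSUM62 score of an amino-acid substitution, vectorised over
#' pairs of one-letter residue codes.
#'
#' @param ref,alt Character vectors of single-letter residue codes.
#' @return Numeric vector of substitution scores.
#' @export
#' @examples
#' blosum62("A", "S")
blosum62 <- function(ref, alt) {
  m <- blosum62_matrix()
  m[cbind(match(ref, rownames(m)), match(alt, colnames(m)))]
}
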