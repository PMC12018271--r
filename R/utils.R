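# internal helpers

# Run code with a temporary RNG state so callers' streams are untouched.
withLocalSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (abs(seed) >= 2^31) stop("seed must be a 32-bit integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# canonical (lexicographically sorted) gene-pair key
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

elementKey <- function(guide_a, guide_b) {
  paste(guide_a, guide_b, sep = "\r")
}

makeElementId <- function(guide_a, guide_b) {
  paste(guide_a, guide_b, sep = "|")
}

randomDnaStrings <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

checkColumns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
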