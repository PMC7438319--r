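#' @keywords internal
"_PACKAGE"

# -- validation helpers --------------------------------------------------

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || (strict_lower && x <= lower))
    stopf("`%s` must be %s %s", name, if (strict_lower) ">" else ">=", lower)
  if (x > upper || (strict_upper && x >= upper))
    stopf("`%s` must be %s %s", name, if (strict_upper) "<" else "<=", upper)
  x
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("`seed` must be a single integer")
  as.integer(seed %% .Machine$integer.max)
}

#' Derive a stage-specific random seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from the global seed plus the stage name, so that re-running a
#' configuration is bit-identical while stages stay decorrelated.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in \[0, 2^31).
#' @export
derive_seed <- function(seed, stage) {
  seed <- check_seed(seed)
  s <- as.double(seed %% 2147483629)
  for (c in utf8ToInt(stage)) s <- (s * 31 + c) %% 2147483629
  as.integer(s)
}

# run expr under a local RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# -- small numeric helpers ----------------------------------------------

# shift a matrix by (dy, dx) with reflective padding
shift_matrix <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- seq_len(nr) + dy
  ci <- seq_len(nc) + dx
  # reflect indices back into range (mirror at the borders)
  reflect <- function(i, n) {
    bad <- i < 1L
    if (any(bad)) i[bad] <- 2L - i[bad]
    bad <- i > n
    if (any(bad)) i[bad] <- 2L * n - i[bad]
    pmin(pmax(i, 1L), n)
  }
  m[reflect(ri, nr), reflect(ci, nc), drop = FALSE]
}

# population standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# md5 of an R object's canonical JSON form (provenance hashes)
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                              force = TRUE), f)
  unname(tools::md5sum(f))
}
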