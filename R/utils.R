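# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores whatever state existed before. All stochastic operations in the
#' package funnel through this so that a fixed seed gives bit-identical
#' results without clobbering the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stopf("seed must be a single finite number, got %s", deparse(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a base seed and a stage counter, kept < 2^31.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k) %% 2147483629)
}

# Trapezoid quadrature weights for an arbitrary strictly increasing grid.
# A single-point grid gets unit weight so point-mass (delta) spectra reduce
# to the closed-form ratio.
trapz_weights <- function(x) {
  n <- length(x)
  if (n == 1L) return(1)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}

trapz <- function(x, y) sum(trapz_weights(x) * y)

# TSV writers used for every tabular artefact: plain tab-separated values,
# '#'-prefixed comment header lines, fixed significant digits so reruns are
# byte-identical.
write_tsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 10, format = "g"))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

read_tsv_comments <- function(path) {
  lines <- readLines(path, n = 50L)
  sub("^#\\s*", "", lines[startsWith(lines, "#")])
}
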