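# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = env)
    on.exit({
      if (had) assign(".Random.seed", old, envir = env)
      else if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' @importFrom utils write.table
writeTSV <- function(df, path, round = 6L) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, round))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @importFrom utils read.delim
readTSV <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

# Title-case fallback for human -> rodent symbol style (ABCC3 -> Abcc3).
titleCaseSymbol <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), tolower(substring(x, 2L)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
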