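#' Stable 32-bit string hash
#'
#' Deterministic polynomial hash used to derive per-unit seeds from a master
#' seed and identifiers, so per-trait and per-orthogroup results never depend
#' on processing order or parallel schedule.
#'
#' @param ... values pasted (with a separator) into the hashed string.
#' @return A non-negative integer below 2^31 - 1.
#' @export
stableHash <- function(...) {
  s <- paste(unlist(list(...)), collapse = "\r")
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483629
  as.integer(h)
}

# Evaluate expr with a locally set RNG seed, restoring global state after.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

# All floating point written to disk uses 6 significant digits.
fmt6 <- function(x) {
  out <- character(length(x))
  na <- is.na(x)
  out[na] <- "NA"
  out[!na & is.infinite(x)] <- ifelse(x[!na & is.infinite(x)] > 0, "Inf", "-Inf")
  fin <- !na & is.finite(x)
  out[fin] <- trimws(formatC(signif(x[fin], 6), format = "g", digits = 6))
  out
}

# Clamp p-values away from zero before log transforms.
pFloor <- function(p) pmax(p, 1e-300)

writeTsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt6)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
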