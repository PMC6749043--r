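#' Path to a packaged fixture file
#'
#' Convenience accessor for the delimited-text fixtures shipped under
#' \code{inst/extdata} (biomarker tables, resonance library, pathway graphs,
#' compound and protein maps).
#'
#' @param ... path components below \code{extdata}.
#' @return Absolute path to the fixture.
#' @export
nmrmetab_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "nmrmetab", mustWork = FALSE)
  if (!nzchar(path)) {
    stop("fixture not found under extdata: ", file.path(...), call. = FALSE)
  }
  path
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed for the duration of \code{expr} and restores the caller's
#' RNG state afterwards, so package functions are deterministic without
#' clobbering the session's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
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
  expr
}

#' Normalize metabolite names for matching
#'
#' Case-insensitive, whitespace/markup-insensitive canonical form, with an
#' alias map so e.g. "LDL/VLDL" and "VLDL/LDL" match.
#'
#' @param x character vector of metabolite names.
#' @return canonical character vector.
#' @export
normalize_metabolite <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out <- gsub("\\*", "", out)        # markdown emphasis in transcriptions
  out <- gsub("[[:space:]]+", " ", out)
  aliases <- c(
    "vldl/ldl"  = "ldl/vldl",
    "ldl-vldl"  = "ldl/vldl",
    "myo-inositol" = "myo-inositol",
    "myoinositol"  = "myo-inositol",
    "nn-dimethylglycine" = "n,n-dimethylglycine"
  )
  hit <- out %in% names(aliases)
  out[hit] <- aliases[out[hit]]
  out
}

# derive a per-stage seed from one pipeline seed so that toggling stages
# does not shift other stages' random streams; kept below 2^31 - 1
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 10007 + h) %% 2147483646 + 1)
}
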