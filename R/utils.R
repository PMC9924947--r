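#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_number <- function(x, name, positive = FALSE, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0) stopf("'%s' must be positive", name)
  if (x < min || x > max) stopf("'%s' must be in [%s, %s]", name, min, max)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min)
    stopf("'%s' must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

#' Derive a reproducible sub-seed from a master seed and string tags
#'
#' Each randomized arm of a simulated cohort draws from its own stream whose
#' seed is a deterministic hash of the master seed and the arm's identifiers
#' (strain, assay, purpose). Outputs are therefore independent of the order in
#' which arms are generated.
#'
#' @param master integer master seed.
#' @param ... character or numeric tags identifying the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(master, ...) {
  tags <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(tags)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Significance stars for a p-value
#'
#' Conventional annotation: `*` below 0.05, `**` below 0.01, `***` below 0.001.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star annotations (empty string when p >= 0.05).
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

# shared cache (Dunnett Monte-Carlo reference samples)
.stresspan_cache <- new.env(parent = emptyenv())
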