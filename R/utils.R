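# Internal helpers shared across modules.

#' Length of the mitochondrial reference genome in base pairs
#' @keywords internal
MT_GENOME_LENGTH <- 16569L

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Validate 1-based mitochondrial coordinates
#'
#' @param position integer vector of 1-based positions.
#' @return the positions as integers, invisibly checked.
#' @keywords internal
assert_mt_position <- function(position) {
  if (length(position) == 0) return(integer(0))
  if (!is.numeric(position) || anyNA(position) ||
      any(position != floor(position))) {
    stopf("coordinate error: positions must be whole numbers, got %s",
          paste(utils::head(position, 3), collapse = ", "))
  }
  bad <- position < 1 | position > MT_GENOME_LENGTH
  if (any(bad)) {
    stopf("coordinate error: position %s outside valid range 1..%d",
          paste(unique(position[bad]), collapse = ", "), MT_GENOME_LENGTH)
  }
  as.integer(position)
}

assert_base <- function(x, what = "base") {
  ok <- is.character(x) & x %in% c("A", "C", "G", "T")
  if (!all(ok)) {
    stopf("sequence-alphabet error: %s must be one of A,C,G,T, got '%s'",
          what, paste(unique(x[!ok]), collapse = "','"))
  }
  x
}

#' Derive a deterministic sub-seed for a named pipeline stage
#'
#' All randomness in the package flows from one master seed; each stage
#' draws from its own substream so partial re-runs stay reproducible.
#' The result is kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @keywords internal
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) %% 1e6 * 7919 + h * 131) %% 2147483647)
}

# complement of A/C/G/T character vectors
comp_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[x])
}

revcomp_chars <- function(x) rev(comp_base(x))
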