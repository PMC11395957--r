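#' Derive a reproducible sub-seed from a root seed and a stream name
#'
#' All randomness in the package flows from one root seed; independent
#' stages (simulation, fold plans, replicates) draw from named substreams so
#' that adding a stage never perturbs the stream of another.
#'
#' @param seed integer root seed.
#' @param name character stream name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_len(nchar(name)))
  as.integer((abs(seed) * 10007 + h * 2654435 + 12345) %% .Machine$integer.max)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# shared log sink: message() plus optional file
.sgp_log <- function(..., logfile = NULL) {
  txt <- paste0(...)
  message(txt)
  if (!is.null(logfile)) cat(txt, "\n", file = logfile, append = TRUE, sep = "")
  invisible(txt)
}
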