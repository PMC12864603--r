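# Shared constants and small helpers.

#' The 20 standard amino-acid one-letter codes, alphabetical
#'
#' Tokenization maps these to integer codes 0..19 in this order; index 20 is
#' reserved for padding.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' @rdname AA_ALPHABET
#' @export
PAD_INDEX <- 20L

#' @rdname AA_ALPHABET
#' @export
MAX_PEPTIDE_LENGTH <- 50L

MIN_PEPTIDE_LENGTH <- 2L

#' Derive a component seed from a global seed
#'
#' A single run seed fans out to deterministic per-component seeds via a fixed
#' integer hash of a component tag, so adding components never reshuffles the
#' random streams of existing ones.
#'
#' @param seed Integer global seed.
#' @param tag Character component tag.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "folds")
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double range
  h <- (abs(seed) %% m)
  for (code in utf8ToInt(tag)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

stop_aopred <- function(msg, class, ...) {
  abort(msg, class = c(class, "aopred_error"), ...)
}
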