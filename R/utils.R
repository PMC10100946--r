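# Internal helpers: error classes, seed streams, matrix/tibble conversion.

abort_config <- function(msg, ...) {
  abort(msg, class = "oralgut_config_error", ...)
}

abort_input <- function(msg, ...) {
  abort(msg, class = "oralgut_input_error", ...)
}

abort_format <- function(msg, ...) {
  abort(msg, class = c("oralgut_format_error", "oralgut_input_error"), ...)
}

abort_runtime <- function(msg, ...) {
  abort(msg, class = "oralgut_runtime_error", ...)
}

#' Derive a named substream seed from a root seed
#'
#' All randomness in the package flows from a single root seed through named
#' substreams (one per stage: catalogue construction, baseline compositions,
#' enrichment dropout, sequencing per sample, ...), so any stage can be re-run
#' in isolation and still reproduce its draws.
#'
#' @param root Integer root seed.
#' @param name Character stream name.
#' @return An integer seed in `[0, 2^31 - 2]`, deterministic in `(root, name)`.
#' @export
#' @examples
#' stream_seed(42, "catalogue")
stream_seed <- function(root, name) {
  stopifnot(is.numeric(root), length(root) == 1, is.character(name))
  m <- 2147483647 # 2^31 - 1, keeps every derived seed a valid 32-bit integer
  h <- 0
  for (ch in utf8ToInt(paste(name, collapse = "/"))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer((abs(root) %% m + (h * 48271) %% m) %% m)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
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
  set.seed(as.integer(seed))
  force(code)
}

# Sample columns of a wide abundance tibble (everything after the id column).
sample_cols <- function(x) {
  setdiff(names(x), names(x)[1])
}

# Wide tibble (id column first) -> numeric matrix with rownames.
tbl_to_matrix <- function(x) {
  ids <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_to_tbl <- function(m, id_name) {
  out <- as_tibble(m, .name_repair = "minimal")
  bind_cols(tibble(!!id_name := rownames(m)), out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
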