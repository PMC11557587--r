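#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(msg, class) {
  stop(structure(class = c(class, "betapet_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(ok, msg, class = "betapet_input_error") {
  if (!isTRUE(ok)) abort(msg, class)
  invisible(TRUE)
}

#' MD5 checksum of a file
#' @param path file path
#' @return unnamed character checksum
#' @keywords internal
file_md5 <- function(path) unname(tools::md5sum(path))

# deterministic child seed derived from a user seed; kept < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
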