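#' Derive a stage-specific random seed from a run seed
#'
#' Every stochastic step in the package draws its own seed from the global
#' run seed plus a stage label, so that stages are reproducible in isolation
#' and adding a stage never perturbs the random stream of another. All
#' arithmetic stays well below 2^53 so the result is exact, and the returned
#' value fits in a 32-bit integer.
#'
#' @param seed integer run seed.
#' @param stage character label of the stage.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(paste(stage, collapse = "/"))) {
    h <- (h * 131 + ch) %% 1000003
  }
  as.integer(((abs(as.numeric(seed)) %% 2147480000) + h * 2011) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count_vector <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x >= 0) && all(x == round(x))
}

abort2 <- function(msg, class) {
  stop(structure(
    class = c(class, "hostclass_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
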