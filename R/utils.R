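#' @useDynLib tacesig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef glm optim pchisq pnorm pt qnorm rbinom rexp rnorm
#'   runif sd t.test var cor predict plogis qlogis setNames uniroot
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ts <- function(...) stop(..., call. = FALSE)

#' Derive a child seed from a master seed
#'
#' Deterministically maps a master seed plus a stage label and index to a
#' 32-bit integer seed, so each pipeline stage and resampling iteration gets
#' an independent but reproducible random stream.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @param index integer index within the stage (default 0).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  # small deterministic string hash (djb2) folded with seed and index
  h <- 5381
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 33 + ch) %% 2147483647
  as.integer((abs(seed) * 2654435 + h + 7919 * index) %% 2147483647)
}

with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

is_binary01 <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1))
}

as_label01 <- function(labels, n = NULL) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    lv <- sort(unique(labels))
    if (!all(lv %in% c("response", "nonresponse")))
      stop_ts("character labels must be 'response'/'nonresponse'")
    labels <- as.numeric(labels == "nonresponse")
  }
  if (!is_binary01(labels)) stop_ts("labels must be binary 0/1 (1 = nonresponse)")
  if (!is.null(n) && length(labels) != n)
    stop_ts("labels length (", length(labels), ") does not match sample count (", n, ")")
  labels
}
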