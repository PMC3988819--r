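#' Derive a reproducible child seed
#'
#' Stages of the pipeline (calibration, imputation, model fitting, ...) each
#' draw their randomness from a child seed derived from one master seed, a
#' stage name and a replicate index, so any stage can be re-run in isolation.
#' The hash is a plain polynomial rolling hash modulo 2^31 - 1, stable across
#' platforms and R versions.
#'
#' @param master integer master seed.
#' @param stage character scalar naming the pipeline stage.
#' @param index non-negative integer replicate index (default 0).
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, "calibrate", 3)
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.character(stage), length(stage) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  vals <- c(abs(as.numeric(master)) %% m, as.numeric(index) %% m,
            as.numeric(utf8ToInt(stage)))
  h <- 17
  for (v in vals) h <- (h * 31 + v) %% m
  # keep strictly inside [1, m - 2] so set.seed always accepts it
  as.integer(h %% (m - 2) + 1)
}

# Skeletal element columns of a measurement table, proximal to distal.
# phIV1..phIV4 are wing-finger (digit IV) phalanges 1-4.
element_columns <- function() {
  c("skull", "mandible", "rostrum", "humerus", "ulna", "radius",
    "mcIV", "phIV1", "phIV2", "phIV3", "phIV4")
}

# Elements summed to a wingspan (one wing's skeletal span); the radius is
# excluded as anatomically parallel to the ulna.
wingspan_elements <- function() {
  c("humerus", "ulna", "mcIV", "phIV1", "phIV2", "phIV3", "phIV4")
}

valid_statuses <- function() c("adult", "subadult", "juvenile")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
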