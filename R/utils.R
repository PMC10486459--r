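`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Each stochastic stage of the pipeline receives its own stream derived
#' from one master seed, so that re-running a single stage reproduces its
#' output without replaying the stages before it.
#'
#' @param master integer master seed.
#' @param offset integer stage offset (each stage uses a distinct one).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, offset) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(offset), length(offset) == 1L)
  # affine map modulo a Mersenne prime keeps streams distinct and < 2^31
  as.integer((as.double(master) * 69069 + as.double(offset) * 10007) %% 2147483647)
}

stop_bcsurv <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "bcsurv_error")))
}

# deterministic per-string seed component (sum of code points, order-weighted)
string_seed <- function(x) {
  v <- utf8ToInt(x)
  as.integer(sum(v * (seq_along(v) %% 97L)) %% 1000003L)
}
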