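#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a local, restorable RNG state
#'
#' All stochastic stages take an explicit integer seed and run under a local
#' RNG so that a call never disturbs the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific child seed from a master seed so that independent
# stages consume independent streams. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 101L, preprocess = 211L, cell_graph = 307L, walks = 401L,
    skipgram = 503L, fallback = 601L, model = 701L, pretrain = 809L,
    centers = 907L, joint = 1009L, kmeans = 1103L, ablate = 1201L
  )
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown stage: ", stage)
  (as.integer(seed) * 2654L + off) %% 2147483629L
}

fmt_num <- function(x) format(x, digits = 6, trim = TRUE)

log_stage <- function(stage, ..., verbose = TRUE) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  message(sprintf("[gcclust] %s | %s", stage, paste0(..., collapse = " ")))
  invisible(NULL)
}

# Quartiles with linear interpolation between order statistics (type 7),
# quartile deviation = (Q3 - Q1) / 2.
quartile_deviation <- function(x) {
  q <- stats::quantile(x, probs = c(0.25, 0.75), names = FALSE, type = 7)
  list(q1 = q[1], q3 = q[2], qd = (q[2] - q[1]) / 2)
}

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))
leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)
sigmoid <- function(x) 1 / (1 + exp(-x))
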