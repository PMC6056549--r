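# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed and a label
#'
#' All stochastic stages of the pipeline draw their seeds through this
#' function, so results are reproducible regardless of the order in which
#' pools or stages are processed. The label (e.g. `"pool3/random"`) is
#' hashed with a polynomial rolling hash and combined with the master
#' seed modulo a prime below 2^31.
#'
#' @param master integer master seed.
#' @param ... character or numeric fragments naming the stage; they are
#'   concatenated with `/` into the hash label.
#' @return An integer seed in `[1, 2147480009]`.
#' @export
derive_seed <- function(master, ...) {
  label <- paste(vapply(list(...), as.character, character(1)),
                 collapse = "/")
  p <- 2147480009 # prime < 2^31
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% p
  as.integer((h + (as.numeric(master) %% p) * 48271) %% p + 1)
}

stop_if_not <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

# trapezoidal quadrature on an ordered grid
trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

is_phylo <- function(x) inherits(x, "phylo")

# root-to-tip depths of all nodes (edge-length units)
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}
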