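# Minimal reverse-mode autodifferentiation tape.
#
# A tape records nodes in creation order during a forward pass; each node
# holds its value, its parent nodes and a backward closure mapping the
# output gradient to parent gradients. ag_backward() sweeps the tape in
# reverse, accumulating gradients into parameter environments.

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  class(e) <- "ag_tape"
  e
}

ag_node <- function(tape, value, parents = list(), backfn = NULL,
                    param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$param <- param
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

ag_const <- function(tape, value) ag_node(tape, value)

# Leaf node bound to a persistent parameter environment; gradients reaching
# the leaf are added into param$grad.
ag_leaf <- function(tape, param) ag_node(tape, param$value, param = param)

ag_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    g <- nd$grad
    if (is.null(g)) next
    if (!is.null(nd$backfn)) {
      gs <- nd$backfn(g)
      ps <- nd$parents
      for (j in seq_along(ps)) {
        gj <- gs[[j]]
        if (is.null(gj)) next
        p <- ps[[j]]
        p$grad <- if (is.null(p$grad)) gj else p$grad + gj
      }
    }
    if (!is.null(nd$param)) {
      p <- nd$param
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    nd$grad <- NULL
  }
  invisible(NULL)
}

# Persistent learnable parameter.
new_param <- function(value, name = "") {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$name <- name
  class(p) <- "ag_param"
  p
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
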