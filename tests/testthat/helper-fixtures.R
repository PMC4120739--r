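# Shared fixtures: small data generators and hand-built ensembles.

# small correlated-free design with an interacting pair and an additive term
make_toy <- function(n = 80, p = 4, seed = 1, noise = 0.1) {
  set.seed(seed)
  x <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("v", seq_len(p))))
  y <- x[, 1] * x[, 2] + x[, 3] + rnorm(n, 0, noise)
  list(x = x, y = y)
}

# Build a "gbt" object by hand from a list of node tables.  Each tree is a
# data.frame-like list of rows: var (1-based, 0 = leaf), split, left,
# right, value, weight, improvement (1-based child ids, 0 when absent).
manual_gbt <- function(trees, var.names, init = 0, shrinkage = 1) {
  trees <- lapply(trees, function(tr) {
    m <- as.matrix(tr)
    colnames(m) <- c("var", "split", "left", "right", "value", "weight",
                     "improvement")
    storage.mode(m) <- "double"
    m
  })
  structure(list(init = init, trees = trees, fitted = NULL,
                 n.trees = length(trees), depth = NA_integer_,
                 shrinkage = shrinkage, bag.fraction = 1, loss = "squared",
                 min.obs = 1L, var.names = var.names, y = NULL, call = NULL),
            class = "gbt")
}

# depth-2 tree encoding f(x) = xj * xk on {-1, +1} coordinates:
# split on j at 0, then on k at 0 in both branches, leaf values +-1
product_tree <- function(j, k) {
  rbind(
    c(j, 0,  2, 5, 0,   1.0, 1),    # root: split on xj
    c(k, 0,  3, 4, 0,   0.5, 1),    # xj <= 0: split on xk
    c(0, 0,  0, 0, +1,  0.25, 0),   #   xk <= 0 -> (-)(-) = +1
    c(0, 0,  0, 0, -1,  0.25, 0),   #   xk  > 0 -> (-)(+) = -1
    c(k, 0,  6, 7, 0,   0.5, 1),    # xj  > 0: split on xk
    c(0, 0,  0, 0, -1,  0.25, 0),
    c(0, 0,  0, 0, +1,  0.25, 0)
  )
}

# depth-3 tree encoding the parity f(x) = x1 * x2 * x3 on {-1, +1}
parity_tree <- function() {
  # nodes listed parent-before-children
  rbind(
    c(1, 0,  2,  9, 0,  1.0,   1),
    c(2, 0,  3,  6, 0,  0.5,   1),
    c(3, 0,  4,  5, 0,  0.25,  1),
    c(0, 0,  0,  0, -1, 0.125, 0),  # (-)(-)(-) = -1
    c(0, 0,  0,  0, +1, 0.125, 0),  # (-)(-)(+) = +1
    c(3, 0,  7,  8, 0,  0.25,  1),
    c(0, 0,  0,  0, +1, 0.125, 0),  # (-)(+)(-) = +1
    c(0, 0,  0,  0, -1, 0.125, 0),  # (-)(+)(+) = -1
    c(2, 0, 10, 13, 0,  0.5,   1),
    c(3, 0, 11, 12, 0,  0.25,  1),
    c(0, 0,  0,  0, +1, 0.125, 0),  # (+)(-)(-) = +1
    c(0, 0,  0,  0, -1, 0.125, 0),  # (+)(-)(+) = -1
    c(3, 0, 14, 15, 0,  0.25,  1),
    c(0, 0,  0,  0, -1, 0.125, 0),  # (+)(+)(-) = -1
    c(0, 0,  0,  0, +1, 0.125, 0)   # (+)(+)(+) = +1
  )
}

# balanced full-factorial +-1 design over p variables
pm_design <- function(p) {
  g <- as.matrix(expand.grid(rep(list(c(-1, 1)), p)))
  colnames(g) <- paste0("x", seq_len(p))
  g
}

# fast small parameter set for fits inside loops
quick_params <- function(...) {
  utils::modifyList(list(n.trees = 60L, depth = 2L, shrinkage = 0.1,
                         bag.fraction = 1, min.obs = 5L), list(...))
}
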