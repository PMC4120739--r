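#' Serialize a boosted ensemble to JSON
#'
#' Writes the full ensemble -- initial constant, shrinkage, loss, training
#' column names and every tree's node table (split variable, threshold,
#' children, value, training-weight fraction, split improvement) -- to a
#' documented JSON format that round-trips through [gbt_from_json()].
#'
#' @param object a [gbt()] fit.
#' @param path output file; `NULL` returns the JSON string.
#' @return the path (or JSON string), invisibly.
#' @export
gbt_to_json <- function(object, path = NULL) {
  stopifnot(inherits(object, "gbt"))
  payload <- list(
    format = "mixboost-gbt-1",
    init = object$init,
    shrinkage = object$shrinkage,
    bag.fraction = object$bag.fraction,
    loss = object$loss,
    depth = object$depth,
    min.obs = object$min.obs,
    n.trees = object$n.trees,
    var.names = object$var.names,
    trees = lapply(object$trees, function(tr) {
      list(var = as.integer(tr[, 1]), split = tr[, 2],
           left = as.integer(tr[, 3]), right = as.integer(tr[, 4]),
           value = tr[, 5], weight = tr[, 6], improvement = tr[, 7])
    })
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Restore a boosted ensemble from JSON
#'
#' @param path file written by [gbt_to_json()], or a JSON string.
#' @return object of class `"gbt"` (without training data: `fitted`,
#'   `y` and `call` are absent, so only prediction, partial dependence,
#'   importance and H computations are available).
#' @export
gbt_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
  if (!identical(payload$format, "mixboost-gbt-1"))
    stop("not a mixboost ensemble JSON file")
  trees <- lapply(payload$trees, function(tr) {
    m <- cbind(var = as.numeric(tr$var), split = as.numeric(tr$split),
               left = as.numeric(tr$left), right = as.numeric(tr$right),
               value = as.numeric(tr$value), weight = as.numeric(tr$weight),
               improvement = as.numeric(tr$improvement))
    m
  })
  structure(list(init = payload$init, trees = trees, fitted = NULL,
                 n.trees = as.integer(payload$n.trees),
                 depth = as.integer(payload$depth),
                 shrinkage = payload$shrinkage,
                 bag.fraction = payload$bag.fraction,
                 loss = payload$loss,
                 min.obs = as.integer(payload$min.obs),
                 var.names = payload$var.names,
                 y = NULL, call = NULL),
            class = "gbt")
}
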